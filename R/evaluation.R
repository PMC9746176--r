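#' Build the CBCT evaluation ROI
#'
#' The HU/dose evaluation region: the CBCT field of view eroded by
#' `marginMm` (2 cm by default), intersected with the BODY contour. The
#' erosion is 3-D (it shortens the cylinder axially as well as radially);
#' set `inPlaneOnly = TRUE` to restrict it to the axial plane.
#'
#' @param fovMask FOV [ROIMask-class]
#' @param body BODY [ROIMask-class] on the same grid
#' @param marginMm erosion margin, mm
#' @param inPlaneOnly restrict the erosion to the axial plane
#' @return an [ROIMask-class] named `"CBCT_ROI"`; a warning is raised if it
#'   is empty
#' @export
buildCbctRoi <- function(fovMask, body, marginMm = 20, inPlaneOnly = FALSE) {
    stopUnlessSameGrid(fovMask, body, "fov and body mask")
    roi <- intersectMasks(erodeMask(fovMask, marginMm, inPlaneOnly), body,
                          name = "CBCT_ROI")
    if (!any(roi@membership))
        warning("CBCT-ROI is empty (body lies outside the eroded FOV)")
    roi
}

#' Mean absolute HU error over an ROI
#'
#' `MAE = sum_i |ref(i) - test(i)| / n` over the `n` voxels of the ROI.
#'
#' @param ref reference [ScalarVolume-class] (the repeat CT in the
#'   evaluation workflow)
#' @param test evaluated [ScalarVolume-class]
#' @param roi [ROIMask-class] with at least one voxel
#' @return scalar MAE (HU)
#' @export
computeMAE <- function(ref, test, roi) {
    stopUnlessSameGrid(ref, test, "ref and test")
    stopUnlessSameGrid(ref, roi, "volumes and roi")
    m <- roi@membership
    if (!any(m)) stop("ROI is empty; MAE is undefined")
    mean(abs(ref@values[m] - test@values[m]))
}

#' Mean signed HU error over an ROI
#'
#' `ME = sum_i (ref(i) - test(i)) / n`; the sign convention is reference
#' minus evaluated, so a test image that is too bright gives a negative ME.
#'
#' @inheritParams computeMAE
#' @return scalar ME (HU)
#' @export
computeME <- function(ref, test, roi) {
    stopUnlessSameGrid(ref, test, "ref and test")
    stopUnlessSameGrid(ref, roi, "volumes and roi")
    m <- roi@membership
    if (!any(m)) stop("ROI is empty; ME is undefined")
    mean(ref@values[m] - test@values[m])
}

#' Two-sample pooled-variance t-test for cohort comparisons
#'
#' Two-tailed Student's t-test with independent samples and equal
#' variances. If both samples are constant: p = 1 when the means agree
#' (nothing to detect), otherwise t = Inf, p = 0.
#'
#' @param a,b numeric vectors of per-case values (length >= 2 each)
#' @return `list(statistic, p.value)`
#' @export
cohortTTest <- function(a, b) {
    if (length(a) < 2L || length(b) < 2L)
        stop("each sample needs at least 2 values")
    if (var(a) + var(b) == 0) {
        if (isTRUE(all.equal(mean(a), mean(b))))
            return(list(statistic = 0, p.value = 1))
        return(list(statistic = Inf, p.value = 0))
    }
    tt <- t.test(a, b, var.equal = TRUE)
    list(statistic = unname(tt$statistic), p.value = tt$p.value)
}
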