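#' HU-override correction by automatic multilevel thresholding
#'
#' Places `nClasses - 1` thresholds by exact multilevel Otsu (dynamic
#' programming on a 1-HU-resolution histogram of the grey levels inside
#' BODY, intersected with the FOV when given, so that outside-FOV air
#' padding does not dominate the air class), partitions the grey-level
#' range into ordered classes and assigns each voxel the mass density of
#' its class. The raw CBCT grey levels are retained unaltered alongside
#' the class volume; HU accuracy metrics for this method are computed on
#' the raw grey levels. Ties at a threshold go to the lower class.
#'
#' @param cbct CBCT [ScalarVolume-class]
#' @param body BODY [ROIMask-class] on the CBCT grid
#' @param table a [DensityClassTable-class] (default: air, lung, adipose,
#'   tissue, cartilage/bone, other at 0.00121/0.26/0.95/1.05/1.6/3 g/cm^3)
#' @param fov optional FOV [ROIMask-class]
#' @return a [CorrectedImage-class] with method `"CBCT_HU"`
#' @export
correctHuOverride <- function(cbct, body, table = densityClassTable(),
                              fov = NULL) {
    stopUnlessSameGrid(cbct, body, "cbct and body mask")
    domain <- body@membership
    if (!is.null(fov)) {
        stopUnlessSameGrid(cbct, fov, "cbct and fov mask")
        domain <- domain & fov@membership
    }
    k <- length(table@density)
    vals <- round(cbct@values[domain])
    if (length(unique(vals)) < k)
        stop("fewer than ", k, " distinct grey levels inside the ",
             "thresholding domain; cannot place ", k - 1,
             " thresholds - use a table with fewer classes")
    lo <- min(vals)
    counts <- tabulate(vals - lo + 1L)
    centers <- lo + seq_along(counts) - 1
    starts <- cpp_multiotsu(as.numeric(counts), centers, k)
    thresholds <- centers[starts[-1]] - 0.5
    cls <- array(1L, cbct@grid@dims)
    for (t in thresholds) cls <- cls + (cbct@values > t)
    new("CorrectedImage", method = "CBCT_HU", hu = NULL,
        classes = ScalarVolume(array(as.numeric(cls), cbct@grid@dims),
                               cbct@grid, "label"),
        classTable = table, raw = cbct,
        provenance = list(thresholds = thresholds,
                          domainVoxels = sum(domain)))
}

#' Estimate a CBCT-to-CT grey-level conversion from a joint histogram
#'
#' Builds the 2-D histogram of (CBCT grey level, CT HU) pairs over the mask
#' (each axis binned over its own 1st-99th percentile range), takes the
#' modal CT HU of every sufficiently populated CBCT-bin column as a tissue
#' pair, enforces monotonicity by pool-adjacent-violators, and returns the
#' surviving anchors as a piecewise-linear [ConversionFunction-class] with
#' clamped extrapolation.
#'
#' @param cbct CBCT [ScalarVolume-class]
#' @param ctDeformed CT [ScalarVolume-class] deformed onto the CBCT grid
#' @param mask [ROIMask-class] over which pairs are collected
#' @param nBins histogram bins per axis
#' @param supportFrac minimum column population as a fraction of the masked
#'   voxel count
#' @return a [ConversionFunction-class]
#' @export
estimateConversion <- function(cbct, ctDeformed, mask, nBins = 64L,
                               supportFrac = 0.001) {
    stopUnlessSameGrid(cbct, ctDeformed, "cbct and deformed CT")
    stopUnlessSameGrid(cbct, mask, "cbct and mask")
    m <- mask@membership
    if (!any(m)) stop("mask is empty; cannot estimate a conversion")
    xv <- cbct@values[m]
    yv <- ctDeformed@values[m]
    rx <- quantile(xv, c(0.01, 0.99), names = FALSE)
    ry <- quantile(yv, c(0.01, 0.99), names = FALSE)
    if (diff(rx) <= 0 || diff(ry) <= 0)
        stop("degenerate grey-level range inside the mask")
    bwx <- diff(rx) / nBins
    bwy <- diff(ry) / nBins
    keep <- xv >= rx[1] & xv <= rx[2] & yv >= ry[1] & yv <= ry[2]
    ix <- pmin(nBins, floor((xv[keep] - rx[1]) / bwx) + 1L)
    iy <- pmin(nBins, floor((yv[keep] - ry[1]) / bwy) + 1L)
    counts <- matrix(tabulate((ix - 1L) * nBins + iy, nbins = nBins * nBins),
                     nrow = nBins) # rows: CT bins, cols: CBCT bins
    support <- colSums(counts)
    minN <- supportFrac * sum(m)
    cols <- which(support >= pmax(1, minN))
    if (length(cols) < 2L)
        stop("fewer than 2 populated joint-histogram columns; cannot ",
             "estimate a conversion")
    ax <- rx[1] + (cols - 0.5) * bwx
    ay <- ry[1] + (apply(counts[, cols, drop = FALSE], 2, which.max) - 0.5) *
        bwy
    ay <- isoreg(ax, ay)$yf # pool-adjacent-violators monotonisation
    new("ConversionFunction", x = as.numeric(ax), y = as.numeric(ay))
}

#' Evaluate a conversion function
#'
#' @param conv a [ConversionFunction-class]
#' @param x numeric vector or [ScalarVolume-class]
#' @return same kind as `x`, mapped through the anchors with clamped
#'   extrapolation
#' @export
applyConversion <- function(conv, x) {
    if (is(x, "ScalarVolume")) {
        out <- approx(conv@x, conv@y, xout = as.numeric(x@values),
                      rule = 2)$y
        return(ScalarVolume(array(out, x@grid@dims), x@grid, x@quantity))
    }
    approx(conv@x, conv@y, xout = x, rule = 2)$y
}

#' Analytical correction and conversion of a CBCT
#'
#' Iterative two-part correction: (1) deformably align the planning CT to
#' the current corrected CBCT (or reuse an injected ground-truth field);
#' (2) estimate and apply the grey-level [ConversionFunction-class]; (3)
#' form the difference map (deformed CT minus current CBCT) inside the FOV,
#' low-pass filter it (Gaussian, `lpFwhmMm` full width at half maximum) and
#' add it back to remove residual low-frequency shading. Iterations that
#' increase the masked MAE against the deformed CT are rejected and the
#' loop stops at the best image.
#'
#' @param cbct CBCT [ScalarVolume-class]
#' @param pct planning CT [ScalarVolume-class] on the same grid (coarsely
#'   aligned)
#' @param body BODY [ROIMask-class] on the CBCT grid
#' @param fov FOV [ROIMask-class]
#' @param field optional injected ground-truth [DeformationField-class]
#'   mapping the planning CT onto the CBCT anatomy (bypasses registration)
#' @param nBins joint-histogram bins for the conversion estimate
#' @param lpFwhmMm low-pass filter FWHM for the shading correction
#' @param nIter number of correction iterations (0 returns the input)
#' @param ... further arguments to [registerDeformable()]
#' @return a [CorrectedImage-class] with method `"CBCT_CC"`
#' @export
correctAnalytical <- function(cbct, pct, body, fov, field = NULL,
                              nBins = 64L, lpFwhmMm = 25, nIter = 3L, ...) {
    stopUnlessSameGrid(cbct, pct, "cbct and planning CT")
    stopUnlessSameGrid(cbct, body, "cbct and body mask")
    stopUnlessSameGrid(cbct, fov, "cbct and fov mask")
    g <- cbct@grid
    fovm <- fov@membership
    # conversion support: the whole FOV, so the air column anchors the low
    # end of the grey-level range; the acceptance gate uses body & FOV
    supp <- ROIMask(body@membership & fovm, g, "support")
    current <- cbct@values
    maeTrace <- numeric(0)
    bestMae <- Inf
    itDone <- 0L
    if (nIter > 0) for (it in seq_len(nIter)) {
        cur <- ScalarVolume(current, g, "HU")
        f <- if (is.null(field))
            registerDeformable(cur, pct, focusMask = fov, ...)
        else field
        pctDef <- applyTransform(pct, f)
        conv <- estimateConversion(cur, pctDef, fov, nBins = nBins)
        cand <- current
        cand[fovm] <- applyConversion(conv, current[fovm])
        diff <- array(0, g@dims)
        diff[fovm] <- pctDef@values[fovm] - cand[fovm]
        lp <- gaussianSmooth(ScalarVolume(diff, g, "HU"),
                             sigmaMm = lpFwhmMm / (2 * sqrt(2 * log(2))),
                             mask = fov)
        cand[fovm] <- cand[fovm] + lp@values[fovm]
        mae <- mean(abs(pctDef@values[supp@membership] -
                        cand[supp@membership]))
        maeTrace <- c(maeTrace, mae)
        if (mae > bestMae) break
        bestMae <- mae
        current <- cand
        itDone <- it
    }
    new("CorrectedImage", method = "CBCT_CC",
        hu = ScalarVolume(current, g, "HU"), classes = NULL,
        classTable = NULL, raw = cbct,
        provenance = list(maeTrace = maeTrace, iterations = itDone,
                          nBins = nBins, lpFwhmMm = lpFwhmMm))
}

#' Detect air pockets inside the body contour
#'
#' Connected components (6-connectivity) of sub-threshold voxels inside
#' BODY whose volume reaches `minVolumeCc`.
#'
#' @param volume HU [ScalarVolume-class]
#' @param body BODY [ROIMask-class]
#' @param huThreshold voxels below this HU are air candidates
#' @param minVolumeCc minimum component volume, cm^3
#' @return an [ROIMask-class] of detected pockets (possibly empty)
#' @export
detectAirPockets <- function(volume, body, huThreshold = -300,
                             minVolumeCc = 0.5) {
    stopUnlessSameGrid(volume, body, "volume and body mask")
    cand <- volume@values < huThreshold & body@membership
    g <- volume@grid
    if (!any(cand))
        return(ROIMask(array(FALSE, g@dims), g, "air_pockets"))
    lab <- cpp_label3d(as.logical(cand), g@dims)
    sizes <- tabulate(lab[lab > 0L])
    keepLabels <- which(sizes * voxelVolumeCc(g) >= minVolumeCc)
    keep <- array(lab %in% keepLabels & lab > 0L, g@dims)
    ROIMask(keep, g, "air_pockets")
}

#' Build a virtual CT from the deformed planning CT
#'
#' The planning CT is warped onto the CBCT anatomy; wherever an air pocket
#' is present in either the warped CT or the analytically corrected CBCT,
#' voxel values are replaced by the corrected-CBCT values. Outside the
#' replacement set the virtual CT equals the warped planning CT exactly.
#'
#' @param pct planning CT [ScalarVolume-class]
#' @param cbctCc the `CBCT_CC` [CorrectedImage-class] (required)
#' @param field [DeformationField-class] mapping the planning CT onto the
#'   CBCT grid
#' @param body BODY [ROIMask-class] on the CBCT grid
#' @param huThreshold,minVolumeCc air pocket detection parameters, see
#'   [detectAirPockets()]
#' @return a [CorrectedImage-class] with method `"CT_V"`
#' @export
buildVirtualCt <- function(pct, cbctCc, field, body, huThreshold = -300,
                           minVolumeCc = 0.5) {
    if (is.null(cbctCc) || !is(cbctCc, "CorrectedImage") ||
        cbctCc@method != "CBCT_CC")
        stop("buildVirtualCt requires the analytically corrected CBCT ",
             "(CorrectedImage with method CBCT_CC)")
    warped <- applyTransform(pct, field)
    stopUnlessSameGrid(warped, cbctCc@hu, "warped CT and corrected CBCT")
    pockets <- unionMasks(
        detectAirPockets(warped, body, huThreshold, minVolumeCc),
        detectAirPockets(cbctCc@hu, body, huThreshold, minVolumeCc),
        name = "air_pockets")
    v <- warped@values
    v[pockets@membership] <- cbctCc@hu@values[pockets@membership]
    new("CorrectedImage", method = "CT_V",
        hu = ScalarVolume(v, warped@grid, "HU"), classes = NULL,
        classTable = NULL, raw = cbctCc@raw,
        provenance = list(replacedVoxels = sum(pockets@membership),
                          pockets = pockets))
}
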