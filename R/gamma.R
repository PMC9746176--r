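#' Global 3-D gamma index between two dose distributions
#'
#' For every reference voxel with dose above the inclusion threshold,
#' `gamma` is the minimum over evaluated sample points of
#' `sqrt(dist^2 / dta^2 + (De - Dr)^2 / (dosePct/100 * normDose)^2)`.
#' The dose criterion is global: a percentage of the configured
#' normalisation dose, not of local dose. The evaluated distribution is
#' sampled trilinearly on a sub-voxel lattice (`refine` points per voxel
#' side); candidates are visited in order of increasing distance with an
#' exact early stop, within `capFactor x distMm` of the reference voxel.
#'
#' @param reference reference dose ([DoseVolume-class] or dose
#'   [ScalarVolume-class]); in the evaluation workflow, the repeat-CT dose
#' @param evaluated evaluated dose on the same grid (resample first
#'   otherwise)
#' @param criteria a [GammaCriteria-class]
#' @return a [GammaResult-class]
#' @export
gammaMap <- function(reference, evaluated, criteria) {
    if (!sameGrid(reference, evaluated))
        stop("reference and evaluated dose are on different grids; ",
             "resample the evaluated dose to the reference grid first")
    g <- reference@grid
    incl <- reference@values > criteria@epsilon
    if (!any(incl))
        stop("no reference voxels with dose above the inclusion threshold; ",
             "the gamma passing rate is undefined")
    res <- cpp_gamma(as.numeric(reference@values),
                     as.numeric(evaluated@values), g@dims, g@spacing,
                     criteria@dosePct / 100 * criteria@normDose,
                     criteria@distMm, criteria@refine,
                     criteria@capFactor * criteria@distMm)
    gammaResultFrom(res, g, criteria)
}

#' Exhaustive brute-force gamma (test oracle)
#'
#' Independent reference implementation: the evaluated dose is precomputed
#' on the full refined lattice and the minimum is taken over every lattice
#' point, with no radius cap and no early exit. Intended for small grids
#' (about 24^3 and below).
#'
#' @inheritParams gammaMap
#' @return a [GammaResult-class]
#' @export
gammaBruteForce <- function(reference, evaluated, criteria) {
    if (!sameGrid(reference, evaluated))
        stop("reference and evaluated dose are on different grids")
    g <- reference@grid
    incl <- reference@values > criteria@epsilon
    if (!any(incl))
        stop("no reference voxels with dose above the inclusion threshold; ",
             "the gamma passing rate is undefined")
    res <- cpp_gamma_brute(as.numeric(reference@values),
                           as.numeric(evaluated@values), g@dims, g@spacing,
                           criteria@dosePct / 100 * criteria@normDose,
                           criteria@distMm, criteria@refine)
    gammaResultFrom(res, g, criteria)
}

gammaResultFrom <- function(res, grid, criteria) {
    new("GammaResult",
        gamma = ScalarVolume(array(res$gamma, grid@dims), grid, "gamma"),
        rate = res$rate, nIncluded = res$included, nPassed = res$passed,
        criteria = criteria)
}

#' Gamma passing rates over a sweep of criteria
#'
#' @param reference,evaluated dose volumes on one grid
#' @param criteriaList list of [GammaCriteria-class] (e.g. 2%/2 mm,
#'   3%/3 mm, 5%/5 mm at the configured normalisation dose)
#' @return `data.frame` with columns `dosePct`, `distMm`, `normDose`,
#'   `rate`, `nIncluded`
#' @export
gprSweep <- function(reference, evaluated, criteriaList) {
    stopifnot(length(criteriaList) >= 1L)
    rows <- lapply(criteriaList, function(cr) {
        r <- gammaMap(reference, evaluated, cr)
        data.frame(dosePct = cr@dosePct, distMm = cr@distMm,
                   normDose = cr@normDose, rate = r@rate,
                   nIncluded = r@nIncluded)
    })
    do.call(rbind, rows)
}
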