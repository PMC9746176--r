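#' Acute coronary event risk from mean heart dose
#'
#' Linear-in-dose NTCP surrogate: each age bracket's risk is
#' `baseline * (1 + slopePerGy * MHD)` (%), and a patient's risk is the
#' convex interpolation `(1 - w) * riskMin + w * riskMax` between the
#' > 70 years (minimum-risk) and < 40 years (maximum-risk) brackets,
#' clamped to [0, 100]. The relative slope (7.4% excess risk per Gy by
#' default) is the published linear mean-heart-dose association the model
#' family is built on; the bracket baselines are configuration.
#'
#' @param mhd mean heart dose, Gy (vectorised; must be >= 0)
#' @param model an [ACEModel-class]
#' @param w interpolation weight in [0, 1] (0 = minimum-risk bracket,
#'   1 = maximum-risk bracket)
#' @return ACE risk in %
#' @examples
#' aceRisk(1.64, aceModel(), w = 0.5)
#' @export
aceRisk <- function(mhd, model = aceModel(), w = 0.5) {
    if (any(!is.finite(mhd)) || any(mhd < 0))
        stop("mean heart dose must be finite and >= 0")
    if (!is.finite(w) || w < 0 || w > 1)
        stop("interpolation weight w must lie in [0, 1]")
    clamp <- function(r) pmin(100, pmax(0, r))
    riskMin <- clamp(model@baselineMin * (1 + model@slopePerGy * mhd))
    riskMax <- clamp(model@baselineMax * (1 + model@slopePerGy * mhd))
    clamp((1 - w) * riskMin + w * riskMax)
}

#' Difference in ACE risk between two mean heart doses
#'
#' `aceRisk(mhdB) - aceRisk(mhdA)`; antisymmetric in its dose arguments.
#'
#' @param mhdA,mhdB mean heart doses, Gy
#' @inheritParams aceRisk
#' @return risk difference in percentage points
#' @export
aceDelta <- function(mhdA, mhdB, model = aceModel(), w = 0.5) {
    aceRisk(mhdB, model, w) - aceRisk(mhdA, model, w)
}
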