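#' Treatment plan for the partial-VMAT breast technique
#'
#' Beam geometry and weighting of the modelled clinical technique: 70% of the dose from
#' two tangential conformal fields and 30% from four short VMAT arcs
#' (40-80 degree spans), delivered by the primary-fluence ray-tracing
#' surrogate engine. Gantry angle 0 points anterior (+y) and rotates
#' towards the patient's left (+x at 90 degrees). Apertures are fitted to
#' the CTV projection plus a margin when the plan is finalised on the
#' planning CT, and the plan's monitor-unit analogue (`scale`) is frozen
#' there: recomputing dose on any other image set reuses it unchanged.
#'
#' @slot prescription prescription dose, Gy
#' @slot sad source-axis distance, mm
#' @slot muEff effective linear attenuation coefficient, 1/cm
#' @slot penumbraSigma aperture penumbra sigma, mm
#' @slot apertureMargin aperture margin around the CTV projection, mm
#' @slot conformalWeight fraction of dose from the tangential fields
#' @slot gantryConformal the two tangential gantry angles, degrees
#' @slot arcs list of `c(start, stop)` gantry spans, degrees
#' @slot arcSpacing control-point spacing within arcs, degrees
#' @slot isocenter world mm (set when finalised)
#' @slot beams control-point matrix (set when finalised)
#' @slot scale frozen plan scale, Gy per unit engine output (NA until
#'   finalised)
#' @export
setClass("TreatmentPlan",
    representation(prescription = "numeric", sad = "numeric",
                   muEff = "numeric", penumbraSigma = "numeric",
                   apertureMargin = "numeric", conformalWeight = "numeric",
                   gantryConformal = "numeric", arcs = "list",
                   arcSpacing = "numeric", engine = "character",
                   rayMm = "numeric", stepMm = "numeric",
                   isocenter = "numeric", beams = "ANY", scale = "numeric"),
    validity = function(object) {
        if (object@prescription <= 0) return("prescription must be > 0")
        if (object@conformalWeight <= 0 || object@conformalWeight >= 1)
            return("conformalWeight must lie in (0, 1)")
        if (length(object@gantryConformal) != 2L)
            return("exactly two tangential gantry angles required")
        if (!object@engine %in% c("raycast", "siddon"))
            return("engine must be 'raycast' or 'siddon'")
        for (a in object@arcs) {
            span <- abs(diff(a))
            if (span < 40 - 1e-9 || span > 80 + 1e-9)
                return("arc spans must lie within 40-80 degrees")
        }
        TRUE
    })

#' Construct a [TreatmentPlan-class]
#'
#' Default geometry is for a left-sided case (tangentials at 55/235
#' degrees); `laterality = "right"` mirrors all gantry angles.
#'
#' @param prescription prescription dose, Gy (42.56 for the 16-fraction
#'   scheme; 55.86 for the 21-fraction boost scheme)
#' @param laterality `"left"` or `"right"`
#' @param sad source-axis distance, mm
#' @param muEff effective attenuation coefficient, 1/cm (about 6 MV)
#' @param penumbraSigmaMm aperture penumbra sigma, mm
#' @param apertureMarginMm aperture margin around the CTV projection, mm
#' @param conformalWeight fraction of dose from the two tangential fields
#' @param gantryConformal tangential gantry angles, degrees (left-sided)
#' @param arcs list of arc `c(start, stop)` spans, degrees (left-sided)
#' @param arcSpacingDeg arc control-point spacing, degrees
#' @param engine `"raycast"` (divergent ray-cast with a cumulative depth
#'   lattice; fast) or `"siddon"` (voxel-exact per-voxel ray traversal;
#'   reference). Both implement the same dose model and agree closely; the
#'   engine choice is frozen with the plan so every image set of a case is
#'   computed identically.
#' @param rayMm lateral ray spacing of the ray-cast depth lattice, mm at
#'   the isocenter plane
#' @param stepMm radial sampling step of the ray-cast engine, mm
#' @return a `TreatmentPlan` (not yet finalised)
#' @export
treatmentPlan <- function(prescription = 42.56,
                          laterality = c("left", "right"), sad = 1000,
                          muEff = 0.05, penumbraSigmaMm = 4,
                          apertureMarginMm = 7, conformalWeight = 0.7,
                          gantryConformal = c(55, 235),
                          arcs = list(c(25, 75), c(250, 300), c(90, 140),
                                      c(100, 150)),
                          arcSpacingDeg = 5, engine = c("raycast", "siddon"),
                          rayMm = 2, stepMm = 1.25) {
    laterality <- match.arg(laterality)
    engine <- match.arg(engine)
    if (laterality == "right") {
        gantryConformal <- (360 - gantryConformal) %% 360
        arcs <- lapply(arcs, function(a) rev((360 - a) %% 360))
    }
    new("TreatmentPlan", prescription = prescription, sad = sad,
        muEff = muEff, penumbraSigma = penumbraSigmaMm,
        apertureMargin = apertureMarginMm, conformalWeight = conformalWeight,
        gantryConformal = gantryConformal, arcs = arcs,
        arcSpacing = arcSpacingDeg, engine = engine, rayMm = rayMm,
        stepMm = stepMm, isocenter = rep(NA_real_, 3),
        beams = NULL, scale = NA_real_)
}

engineDose <- function(density, plan) {
    g <- density@grid
    if (plan@engine == "siddon")
        cpp_dose_siddon(as.numeric(density@values), g@dims, g@spacing,
                        g@origin, plan@beams, plan@muEff, plan@penumbraSigma,
                        plan@sad)
    else
        cpp_dose_fast(as.numeric(density@values), g@dims, g@spacing,
                      g@origin, plan@beams, plan@muEff, plan@penumbraSigma,
                      plan@sad, plan@rayMm, plan@stepMm)
}

setMethod("show", "TreatmentPlan", function(object) {
    cat(sprintf("TreatmentPlan %.4g Gy, %d%% conformal / %d%% VMAT (%d arcs)\n",
                object@prescription, round(100 * object@conformalWeight),
                round(100 * (1 - object@conformalWeight)),
                length(object@arcs)))
    if (!is.null(object@beams))
        cat(sprintf("  finalised: %d control points, scale %.4g\n",
                    nrow(object@beams), object@scale))
    else cat("  not finalised (call finalizePlan on the planning CT)\n")
})

#' Default HU-to-mass-density conversion table
#'
#' Monotone piecewise-linear anchors used for dose calculation on HU
#' volumes, clamped outside the anchor range.
#'
#' @param hu anchor HU values
#' @param density anchor densities, g/cm^3
#' @return list with elements `hu`, `density`
#' @export
huDensityTable <- function(hu = c(-1000, 0, 1000, 3000),
                           density = c(0.00121, 1.0, 1.6, 3.0)) {
    stopifnot(length(hu) == length(density), !is.unsorted(hu, strictly = TRUE),
              !is.unsorted(density), all(density >= 0))
    list(hu = hu, density = density)
}

#' Convert an HU volume to mass density
#'
#' @param volume HU [ScalarVolume-class]
#' @param table from [huDensityTable()]
#' @return a density [ScalarVolume-class] (g/cm^3)
#' @export
huToDensity <- function(volume, table = huDensityTable()) {
    out <- approx(table$hu, table$density, xout = as.numeric(volume@values),
                  rule = 2)$y
    ScalarVolume(array(out, volume@grid@dims), volume@grid, "density")
}

#' @describeIn CorrectedImage density volume for dose calculation: class
#'   densities for `CBCT_HU`, HU-to-density conversion of the corrected HU
#'   for `CBCT_CC`/`CT_V`
#' @param x object
#' @param huTable from [huDensityTable()] (ignored for `CBCT_HU`)
#' @export
setMethod("densityVolume", "CorrectedImage", function(x,
                                                      huTable = huDensityTable()) {
    if (x@method == "CBCT_HU") {
        d <- x@classTable@density[as.integer(x@classes@values)]
        return(ScalarVolume(array(d, x@classes@grid@dims), x@classes@grid,
                            "density"))
    }
    huToDensity(x@hu, huTable)
})

#' Override density outside the CBCT field of view
#'
#' Voxels inside the BODY contour but outside the FOV are set to
#' `value` (water, 1 g/cm^3, by default); all other voxels are untouched.
#'
#' @param density density [ScalarVolume-class]
#' @param body BODY [ROIMask-class]
#' @param fov FOV [ROIMask-class]
#' @param value override density, g/cm^3
#' @return a density [ScalarVolume-class]
#' @export
overrideOutsideFov <- function(density, body, fov, value = 1.0) {
    stopUnlessSameGrid(density, body, "density and body")
    stopUnlessSameGrid(density, fov, "density and fov")
    v <- density@values
    v[body@membership & !fov@membership] <- value
    ScalarVolume(v, density@grid, "density")
}

beamBasis <- function(gantryDeg, iso, sad) {
    th <- gantryDeg * pi / 180
    srcDir <- c(sin(th), cos(th), 0)
    src <- iso + sad * srcDir
    axis <- -srcDir
    vhat <- c(0, 0, 1)
    uhat <- c(vhat[2] * axis[3] - vhat[3] * axis[2],
              vhat[3] * axis[1] - vhat[1] * axis[3],
              vhat[1] * axis[2] - vhat[2] * axis[1])
    uhat <- uhat / sqrt(sum(uhat^2))
    list(src = src, axis = axis, uhat = uhat, vhat = vhat)
}

fitAperture <- function(basis, ctvCoords, sad, margin) {
    rel <- sweep(ctvCoords, 2, basis$src)
    ta <- rel %*% basis$axis
    u <- (rel %*% basis$uhat) * sad / ta
    v <- (rel %*% basis$vhat) * sad / ta
    c(umin = min(u) - margin, umax = max(u) + margin,
      vmin = min(v) - margin, vmax = max(v) + margin)
}

#' Finalise a plan on the planning CT
#'
#' Places the isocenter at the CTV centroid, fits every control point's
#' rectangular aperture to the CTV projection plus the aperture margin,
#' computes the unscaled engine dose on the planning-CT density, and
#' freezes the plan scale so that the mean CTV dose equals the
#' prescription. The frozen scale is reused unchanged on every other image
#' set.
#'
#' @param plan a [TreatmentPlan-class]
#' @param density planning-CT density [ScalarVolume-class]
#' @param ctv whole-breast CTV [ROIMask-class]
#' @return the finalised `TreatmentPlan`
#' @export
finalizePlan <- function(plan, density, ctv) {
    stopUnlessSameGrid(density, ctv, "density and CTV")
    g <- density@grid
    m <- which(ctv@membership)
    if (length(m) == 0L) stop("CTV mask is empty")
    idx <- arrayInd(m, g@dims)
    coords <- cbind(voxelCoords(g, 1)[idx[, 1]],
                    voxelCoords(g, 2)[idx[, 2]],
                    voxelCoords(g, 3)[idx[, 3]])
    iso <- colMeans(coords)
    cps <- list()
    wConf <- plan@conformalWeight / length(plan@gantryConformal)
    for (a in plan@gantryConformal)
        cps[[length(cps) + 1L]] <- c(angle = a, weight = wConf)
    wArcTotal <- (1 - plan@conformalWeight) / length(plan@arcs)
    for (arc in plan@arcs) {
        angles <- seq(arc[1], arc[2], by = plan@arcSpacing *
                          sign(arc[2] - arc[1]))
        for (a in angles)
            cps[[length(cps) + 1L]] <- c(angle = a,
                                         weight = wArcTotal / length(angles))
    }
    beams <- matrix(0, nrow = length(cps), ncol = 17)
    for (i in seq_along(cps)) {
        b <- beamBasis(cps[[i]]["angle"], iso, plan@sad)
        ap <- fitAperture(b, coords, plan@sad, plan@apertureMargin)
        beams[i, ] <- c(b$src, b$axis, b$uhat, b$vhat, ap,
                        cps[[i]]["weight"])
    }
    plan@isocenter <- iso
    plan@beams <- beams
    raw <- engineDose(density, plan)
    meanCtv <- mean(raw[m])
    if (meanCtv <= 0)
        stop("CTV receives no dose from any beam; check the plan geometry")
    plan@scale <- plan@prescription / meanCtv
    plan
}

#' Dose volume with plan provenance
#'
#' A dose [ScalarVolume-class] plus the provenance of its calculation.
#'
#' @slot provenance list (plan parameters, normalisation statement)
#' @export
setClass("DoseVolume", contains = "ScalarVolume",
         representation(provenance = "list"))

#' Compute dose with the frozen plan
#'
#' Primary-fluence surrogate: per control point, dose is weight x aperture
#' transmission (error-function penumbra) x exp(-muEff x radiological path
#' from the source, by voxel-exact ray traversal of the density grid) x
#' inverse square, scaled by the plan scale frozen on the planning CT. The
#' plan must have been finalised with [finalizePlan()]; the calculation is
#' deterministic, so identical density inputs give bit-identical dose.
#'
#' @param density density [ScalarVolume-class]
#' @param plan a finalised [TreatmentPlan-class]
#' @return a [DoseVolume-class] (Gy)
#' @export
computeDose <- function(density, plan) {
    if (is.null(plan@beams) || is.na(plan@scale))
        stop("plan is not finalised; call finalizePlan on the planning CT ",
             "first so the plan scale is frozen there")
    g <- density@grid
    raw <- engineDose(density, plan)
    new("DoseVolume", grid = g,
        values = array(raw * plan@scale, g@dims), quantity = "dose",
        provenance = list(prescription = plan@prescription,
                          scale = plan@scale, muEff = plan@muEff,
                          nControlPoints = nrow(plan@beams),
                          normalization = "mean CTV dose on pCT = prescription"))
}

#' Radiological path length from a point source to a point
#'
#' Voxel-exact (Siddon-style) line integral of density along the ray,
#' in g/cm^2-equivalent units (density in g/cm^3, length in cm).
#'
#' @param density density [ScalarVolume-class]
#' @param src,dst world mm coordinates
#' @return scalar path integral
#' @export
radiologicalPath <- function(density, src, dst) {
    g <- density@grid
    cpp_radpath(as.numeric(density@values), g@dims, g@spacing, g@origin,
                as.numeric(src), as.numeric(dst))
}

#' DVH statistics for one ROI
#'
#' Dx is the minimum dose received by the hottest x% of the ROI volume
#' (top-down percentile), computed by sorting voxel doses and linear
#' interpolation between order statistics; `Dmean` is the arithmetic mean.
#' Statistics are reported in Gy and as % of the prescription.
#'
#' @param dose a [DoseVolume-class] or dose [ScalarVolume-class]
#' @param roi [ROIMask-class], non-empty, on the dose grid
#' @param prescription prescription dose, Gy
#' @param levels percentages x for Dx
#' @return one-row `data.frame` with columns `roi`, `n`, `D1`, `D2`, `D95`,
#'   `D98`, `D99`, `Dmean` and matching `*_pct` columns
#' @export
dvhStats <- function(dose, roi, prescription,
                     levels = c(1, 2, 95, 98, 99)) {
    stopUnlessSameGrid(dose, roi, "dose and roi")
    m <- roi@membership
    if (!any(m)) stop("ROI is empty; DVH statistics are undefined")
    d <- sort(dose@values[m])
    n <- length(d)
    dx <- vapply(levels, function(x) {
        r <- 1 + (n - 1) * (1 - x / 100) # fractional rank from the top
        lo <- floor(r); hi <- ceiling(r)
        if (lo < 1) return(d[1])
        if (hi > n) return(d[n])
        d[lo] + (r - lo) * (d[hi] - d[lo])
    }, numeric(1))
    names(dx) <- paste0("D", levels)
    out <- data.frame(roi = roi@name, n = n, prescription = prescription,
                      t(dx), Dmean = mean(d))
    for (nm in c(names(dx), "Dmean"))
        out[[paste0(nm, "_pct")]] <- 100 * out[[nm]] / prescription
    out
}

#' Dose differences relative to the prescription
#'
#' For every image set and DVH statistic:
#' `(value - reference value) / prescription x 100` (%), reported with the
#' repeat CT as reference.
#'
#' @param reference one-row `data.frame` from [dvhStats()] (the repeat CT)
#' @param others named list of [dvhStats()] rows for the other image sets
#' @param prescription prescription dose, Gy (must match the one used for
#'   the DVH rows)
#' @return long `data.frame` with columns `imageSet`, `statistic`,
#'   `diffPct`
#' @export
doseDifferenceReport <- function(reference, others, prescription) {
    stats <- c("D1", "D2", "D95", "D98", "D99", "Dmean")
    rows <- list()
    for (nm in names(others)) {
        o <- others[[nm]]
        if (!identical(o$roi, reference$roi))
            stop("DVH rows compare different ROIs: ", o$roi, " vs ",
                 reference$roi)
        if (abs(o$prescription - prescription) > 1e-9 ||
            abs(reference$prescription - prescription) > 1e-9)
            stop("prescription mismatch between DVH rows and report")
        for (s in stats) {
            rows[[length(rows) + 1L]] <- data.frame(
                imageSet = nm, statistic = s,
                diffPct = 100 * (o[[s]] - reference[[s]]) / prescription)
        }
    }
    do.call(rbind, rows)
}
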