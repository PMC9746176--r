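#' Run the HU-accuracy workflow on one case
#'
#' The scripted image-quality chain: ensure the External contour, align the
#' repeat CT and the CBCT (identity by default, matching the simulated
#' geometry; pass a [RigidTransform-class] or `"estimate"` otherwise),
#' build the CBCT-ROI (FOV minus `roiMarginMm`, intersected with BODY) and
#' copy all structures rigidly to the CBCT, apply the three corrections,
#' and compute MAE/ME for every method and ROI against the repeat CT,
#' including the repeat-CT-vs-planning-CT baseline row.
#'
#' HU metrics use raw grey levels for `CBCT_HU` and the corrected HU for
#' `CBCT_CC`/`CT_V`. With `registration = "truth"` (default) the case's
#' ground-truth deformation field is injected into the analytical
#' correction and virtual CT so correction accuracy is measured with
#' registration error excluded.
#'
#' @param case from [generatePhantomCase()]
#' @param roiMarginMm CBCT-ROI erosion margin, mm
#' @param registration `"truth"` (inject the ground-truth field),
#'   `"estimate"` (demons), or a [DeformationField-class]
#' @param rigid `"identity"`, `"estimate"` or a [RigidTransform-class] for
#'   the rCT-CBCT alignment and structure copy
#' @param nIter analytical-correction iterations
#' @param lpFwhmMm analytical-correction low-pass FWHM, mm
#' @return list with elements `metrics` (data.frame: case, method, roi, n,
#'   mae, me), `corrections`, `cbctRoi`, `structures`, `field`
#' @export
runHuWorkflow <- function(case, roiMarginMm = 20, registration = "truth",
                          rigid = "identity", nIter = 3L, lpFwhmMm = 25) {
    body <- getMask(case$structuresRct, externalName(case$structuresRct))
    fov <- case$fovMask
    rigidTf <- resolveRigid(rigid, case)
    structures <- if (isIdentityRigid(rigidTf)) case$structuresRct
        else applyTransform(case$structuresRct, rigidTf)
    bodyC <- getMask(structures, externalName(structures))
    cbctRoi <- buildCbctRoi(fov, bodyC, marginMm = roiMarginMm)
    field <- resolveField(registration, case)
    corrHu <- correctHuOverride(case$cbct, bodyC, fov = fov)
    corrCc <- correctAnalytical(case$cbct, case$pct, bodyC, fov,
                                field = field, nIter = nIter,
                                lpFwhmMm = lpFwhmMm)
    corrV <- buildVirtualCt(case$pct, corrCc, field, bodyC)
    rois <- list(CBCT_ROI = cbctRoi,
                 whole_breast_CTV = getMask(structures, "whole_breast_CTV"))
    tests <- list(pCT = case$pct, CBCT_HU = huVolume(corrHu),
                  CBCT_CC = huVolume(corrCc), CT_V = huVolume(corrV))
    rows <- list()
    for (rn in names(rois)) for (mn in names(tests)) {
        rows[[length(rows) + 1L]] <- data.frame(
            case = case$seed, method = mn, roi = rn,
            n = voxelCount(rois[[rn]]),
            mae = computeMAE(case$rct, tests[[mn]], rois[[rn]]),
            me = computeME(case$rct, tests[[mn]], rois[[rn]]))
    }
    list(metrics = do.call(rbind, rows),
         corrections = list(CBCT_HU = corrHu, CBCT_CC = corrCc,
                            CT_V = corrV),
         cbctRoi = cbctRoi, structures = structures, field = field)
}

resolveRigid <- function(rigid, case) {
    if (is(rigid, "RigidTransform")) return(rigid)
    if (identical(rigid, "identity")) return(RigidTransform())
    if (identical(rigid, "estimate"))
        return(registerRigid(case$rct, case$cbct))
    stop("rigid must be 'identity', 'estimate' or a RigidTransform")
}

isIdentityRigid <- function(tf) {
    all(abs(tf@rotation) < 1e-12) && all(abs(tf@translation) < 1e-12)
}

resolveField <- function(registration, case) {
    if (is(registration, "DeformationField")) return(registration)
    if (identical(registration, "truth")) return(case$field)
    if (identical(registration, "estimate"))
        return(registerDeformable(case$cbct, case$pct,
                                  focusMask = case$fovMask))
    stop("registration must be 'truth', 'estimate' or a DeformationField")
}

#' Run the dose-evaluation workflow on one case
#'
#' Extends [runHuWorkflow()] with the dose chain: per-method density
#' assignment (class densities for `CBCT_HU`, HU-to-density conversion for
#' the others), density override to 1 g/cm^3 inside BODY but outside the
#' CBCT FOV, frozen-plan dose on every image set (the plan is finalised
#' once on the planning CT), DVH statistics for the whole-breast CTV,
#' boost CTV and heart, dose differences relative to the prescription with
#' the repeat CT as reference, a gamma passing-rate sweep against the
#' repeat-CT dose, and the ACE risk from the mean heart dose.
#'
#' @param case from [generatePhantomCase()]
#' @param hu optionally a precomputed [runHuWorkflow()] result
#' @param plan a [TreatmentPlan-class] (finalised internally on the
#'   planning CT)
#' @param gammaNormDose global gamma normalisation dose, Gy
#' @param gammaSpecs list of `c(dosePct, distMm)` pairs
#' @param huTable HU-to-density table from [huDensityTable()]
#' @param ace an [ACEModel-class]
#' @param aceWeight age-bracket interpolation weight
#' @param ... passed on to [runHuWorkflow()]
#' @return list with `huMetrics`, `dvh`, `doseDiff`, `gpr`, `ace`,
#'   `doses`, `provenance`
#' @export
runDoseWorkflow <- function(case, hu = NULL, plan = treatmentPlan(),
                            gammaNormDose = 42.47,
                            gammaSpecs = list(c(2, 2), c(3, 3), c(5, 5)),
                            huTable = huDensityTable(), ace = aceModel(),
                            aceWeight = 0.5, ...) {
    if (is.null(hu)) hu <- runHuWorkflow(case, ...)
    structures <- hu$structures
    body <- getMask(structures, externalName(structures))
    fov <- case$fovMask
    dens <- list(
        pCT = huToDensity(case$pct, huTable),
        rCT = huToDensity(case$rct, huTable),
        CBCT_HU = densityVolume(hu$corrections$CBCT_HU),
        CBCT_CC = densityVolume(hu$corrections$CBCT_CC, huTable),
        CT_V = densityVolume(hu$corrections$CT_V, huTable))
    for (nm in c("CBCT_HU", "CBCT_CC", "CT_V"))
        dens[[nm]] <- overrideOutsideFov(dens[[nm]], body, fov)
    plan <- finalizePlan(plan, dens$pCT,
                         getMask(case$structuresPct, "whole_breast_CTV"))
    doses <- lapply(dens, computeDose, plan = plan)
    roiNamesDose <- c("whole_breast_CTV", "boost_CTV", "heart")
    dvh <- list()
    for (set in names(doses)) {
        str <- if (set == "pCT") case$structuresPct else structures
        for (rn in roiNamesDose) {
            row <- dvhStats(doses[[set]], getMask(str, rn),
                            plan@prescription)
            row <- cbind(imageSet = set, row)
            dvh[[length(dvh) + 1L]] <- row
        }
    }
    dvh <- do.call(rbind, dvh)
    diffs <- list()
    for (rn in roiNamesDose) {
        ref <- dvh[dvh$imageSet == "rCT" & dvh$roi == rn, ]
        others <- list()
        for (set in setdiff(names(doses), "rCT"))
            others[[set]] <- dvh[dvh$imageSet == set & dvh$roi == rn, ]
        d <- doseDifferenceReport(ref, others, plan@prescription)
        d$roi <- rn
        diffs[[length(diffs) + 1L]] <- d
    }
    doseDiff <- do.call(rbind, diffs)
    criteria <- lapply(gammaSpecs, function(s)
        gammaCriteria(s[1], s[2], normDose = gammaNormDose))
    gpr <- list()
    for (set in c("CBCT_HU", "CBCT_CC", "CT_V")) {
        tab <- gprSweep(doses$rCT, doses[[set]], criteria)
        tab <- cbind(imageSet = set, tab)
        gpr[[length(gpr) + 1L]] <- tab
    }
    gpr <- do.call(rbind, gpr)
    mhd <- setNames(dvh$Dmean[dvh$roi == "heart"],
                    dvh$imageSet[dvh$roi == "heart"])
    aceTab <- data.frame(imageSet = names(mhd), mhd = unname(mhd),
                         risk = aceRisk(unname(mhd), ace, aceWeight))
    aceTab$deltaVsRct <- aceTab$risk - aceTab$risk[aceTab$imageSet == "rCT"]
    list(huMetrics = hu$metrics, dvh = dvh, doseDiff = doseDiff, gpr = gpr,
         ace = aceTab, doses = doses,
         provenance = list(seed = case$seed, prescription = plan@prescription,
                           planScale = plan@scale,
                           gammaNormDose = gammaNormDose,
                           aceWeight = aceWeight))
}

#' Per-case anatomical variation of the cohort
#'
#' A clinical cohort consists of distinct patients who share the inclusion
#' criterion (a breast surface deformation above 5 mm) but differ in
#' anatomy. Each cohort case therefore draws, deterministically from its
#' seed: the deformation peak (uniform 6-12 mm) and direction (swelling or
#' shrinkage), the breast radius (50-60 mm) and lateral position, and a
#' small heart position jitter. Scanner/artifact parameters are properties
#' of the imaging chain and stay fixed across the cohort.
#'
#' @param seed case seed
#' @param params baseline [phantomParams()]
#' @param deform baseline [deformationSpec()]
#' @return `list(params, deform)` for [generatePhantomCase()]
#' @export
cohortCaseConditions <- function(seed, params = phantomParams(),
                                 deform = deformationSpec()) {
    set.seed(as.integer(seed) + 2000L)
    draw <- runif(6)
    deform$peakMm <- 6 + 6 * draw[1]
    deform$mode <- if (draw[2] < 0.5) "swelling" else "shrinkage"
    params$breastRadiusMm <- 50 + 10 * draw[3]
    params$breastCenterMm <- params$breastCenterMm +
        c(10 * (draw[4] - 0.5), 6 * (draw[5] - 0.5), 0)
    params$heartCenterMm <- params$heartCenterMm +
        c(8 * (draw[6] - 0.5), 0, 0)
    list(params = params, deform = deform)
}

#' Run a seeded synthetic cohort
#'
#' Generates one case per seed (per-case anatomy drawn by
#' [cohortCaseConditions()] unless `varyAnatomy = FALSE`), runs the full
#' dose workflow on each, and aggregates per-method summaries (mean, sd,
#' min, max) of the HU metrics, the dose differences relative to the
#' prescription, and the gamma passing rates, plus pooled-variance t-tests
#' of each image set's DVH values against the repeat CT's.
#'
#' @param seeds integer vector of case seeds (>= 2)
#' @param params,deform,artifact study conditions, see
#'   [generatePhantomCase()]
#' @param varyAnatomy draw per-case anatomy from each seed (the cohort
#'   emulates distinct patients); if FALSE every case shares the baseline
#'   anatomy
#' @param ... passed to [runDoseWorkflow()]
#' @param progress print one line per case
#' @return list with `cases` (per-case report tables), `huSummary`,
#'   `doseDiffSummary`, `gprSummary`, `tTests`, `boxplotData`
#' @export
runCohort <- function(seeds, params = phantomParams(),
                      deform = deformationSpec(),
                      artifact = cbctArtifactModel(), varyAnatomy = TRUE,
                      ..., progress = FALSE) {
    if (length(seeds) < 2L) stop("a cohort needs at least 2 cases")
    cases <- vector("list", length(seeds))
    names(cases) <- make.unique(paste0("case_", seeds))
    for (i in seq_along(seeds)) {
        s <- seeds[i]
        if (progress) message("case seed ", s)
        cond <- if (varyAnatomy) cohortCaseConditions(s, params, deform)
            else list(params = params, deform = deform)
        case <- generatePhantomCase(s, cond$params, cond$deform, artifact)
        rep <- runDoseWorkflow(case, ...)
        rep$doses <- NULL # keep reports small
        cases[[i]] <- rep
    }
    agg <- function(x) c(mean = mean(x), sd = sd(x), min = min(x),
                         max = max(x))
    huAll <- do.call(rbind, lapply(cases, `[[`, "huMetrics"))
    huSummary <- do.call(rbind, lapply(
        split(huAll, list(huAll$method, huAll$roi), drop = TRUE),
        function(d) data.frame(method = d$method[1], roi = d$roi[1],
                               t(agg(d$mae)), me_mean = mean(d$me),
                               me_sd = sd(d$me))))
    diffAll <- do.call(rbind, lapply(seq_along(cases), function(i)
        cbind(case = names(cases)[i], cases[[i]]$doseDiff)))
    doseDiffSummary <- do.call(rbind, lapply(
        split(diffAll, list(diffAll$imageSet, diffAll$statistic,
                            diffAll$roi), drop = TRUE),
        function(d) data.frame(imageSet = d$imageSet[1],
                               statistic = d$statistic[1], roi = d$roi[1],
                               t(agg(d$diffPct)))))
    gprAll <- do.call(rbind, lapply(seq_along(cases), function(i)
        cbind(case = names(cases)[i], cases[[i]]$gpr)))
    gprSummary <- do.call(rbind, lapply(
        split(gprAll, list(gprAll$imageSet, gprAll$dosePct), drop = TRUE),
        function(d) data.frame(imageSet = d$imageSet[1],
                               dosePct = d$dosePct[1],
                               distMm = d$distMm[1], t(agg(d$rate)))))
    dvhAll <- do.call(rbind, lapply(seq_along(cases), function(i)
        cbind(case = names(cases)[i], cases[[i]]$dvh)))
    tRows <- list()
    ctv <- dvhAll[dvhAll$roi == "whole_breast_CTV", ]
    refVals <- ctv$Dmean_pct[ctv$imageSet == "rCT"]
    for (set in setdiff(unique(ctv$imageSet), "rCT")) {
        tt <- cohortTTest(ctv$Dmean_pct[ctv$imageSet == set], refVals)
        tRows[[length(tRows) + 1L]] <- data.frame(
            imageSet = set, roi = "whole_breast_CTV",
            statistic = "Dmean_pct", t = tt$statistic, p = tt$p.value)
    }
    list(cases = cases, huSummary = huSummary,
         doseDiffSummary = doseDiffSummary, gprSummary = gprSummary,
         tTests = do.call(rbind, tRows), boxplotData = diffAll)
}
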