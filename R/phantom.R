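#' Parameters of the synthetic thorax phantom
#'
#' Defines a simplified thorax: an elliptic-cylinder body with a
#' subcutaneous adipose shell, two lungs, a heart, a bony spine and ribs,
#' and a breast bulge on the anterior chest wall. Every organ is placed in
#' world mm on the grid's patient convention (+x left, +y anterior,
#' +z cranial); all tissue HU values are configurable.
#'
#' @param dims grid voxels per axis
#' @param spacingMm voxel spacing (mm)
#' @param bodySemiAxesMm in-plane semi-axes of the body cylinder
#' @param bodyCenterMm in-plane center (x, y) of the body cylinder
#' @param adiposeShellMm thickness of the subcutaneous adipose layer
#' @param breastRadiusMm radius of the spherical breast bulge
#' @param breastCenterMm center of the breast bulge (on the anterior surface)
#' @param lungSemiAxesMm per-lung ellipsoid semi-axes
#' @param lungCentersMm list of two lung centers
#' @param heartRadiusMm heart sphere radius
#' @param heartCenterMm heart center
#' @param spineRadiusMm,spineCenterMm bony spine cylinder (along z)
#' @param ribRadiusMm rib rod radius; ribs are placed on the body ellipse
#' @param boostRadiusMm radius of the boost CTV sphere inside the breast
#' @param ctvSkinMarginMm CTVs are contracted to stay this far inside BODY
#' @param huTable named HU values: air, lung, adipose, glandular, soft, bone
#' @param noiseSigmaHu CT noise standard deviation (HU)
#' @param airPocket optional `list(centerMm, radiusMm)` air cavity carved
#'   into the repeat-CT anatomy after deformation
#' @param seed integer seed fixing all randomness
#' @return a named list of validated phantom parameters
#' @export
phantomParams <- function(dims = c(128L, 128L, 64L), spacingMm = 2.5,
                          bodySemiAxesMm = c(100, 70),
                          bodyCenterMm = c(0, -10),
                          adiposeShellMm = 8,
                          breastRadiusMm = 55,
                          breastCenterMm = c(40, 55, 0),
                          lungSemiAxesMm = c(38, 45, 55),
                          lungCentersMm = list(c(-45, -15, 0), c(45, -15, 0)),
                          heartRadiusMm = 35, heartCenterMm = c(12, -5, 0),
                          spineRadiusMm = 12, spineCenterMm = c(0, -60),
                          ribRadiusMm = 5,
                          boostRadiusMm = 14,
                          ctvSkinMarginMm = 5,
                          huTable = c(air = -1000, lung = -750, adipose = -90,
                                      glandular = 20, soft = 40, bone = 700),
                          noiseSigmaHu = 8,
                          airPocket = NULL,
                          seed = 1L) {
    if (length(spacingMm) == 1L) spacingMm <- rep(spacingMm, 3L)
    p <- list(dims = as.integer(dims), spacingMm = spacingMm,
              bodySemiAxesMm = bodySemiAxesMm, bodyCenterMm = bodyCenterMm,
              adiposeShellMm = adiposeShellMm,
              breastRadiusMm = breastRadiusMm,
              breastCenterMm = breastCenterMm,
              lungSemiAxesMm = lungSemiAxesMm,
              lungCentersMm = lungCentersMm,
              heartRadiusMm = heartRadiusMm, heartCenterMm = heartCenterMm,
              spineRadiusMm = spineRadiusMm, spineCenterMm = spineCenterMm,
              ribRadiusMm = ribRadiusMm, boostRadiusMm = boostRadiusMm,
              ctvSkinMarginMm = ctvSkinMarginMm,
              huTable = huTable, noiseSigmaHu = noiseSigmaHu,
              airPocket = airPocket, seed = as.integer(seed))
    stopifnot(all(is.finite(p$huTable)), p$noiseSigmaHu >= 0,
              all(p$bodySemiAxesMm > 0), p$breastRadiusMm > 0)
    # organs must fit inside the grid
    ext <- (p$dims - 1) * p$spacingMm / 2
    if (any(abs(p$bodyCenterMm) + p$bodySemiAxesMm > ext[1:2]))
        stop("body exceeds the grid extent; enlarge the grid or shrink the body")
    if (any(abs(p$breastCenterMm[1:2]) + p$breastRadiusMm > ext[1:2]))
        stop("breast exceeds the grid extent")
    p
}

phantomGrid <- function(params) {
    ImageGrid(params$dims, spacing = params$spacingMm,
              origin = -(params$dims - 1) * params$spacingMm / 2)
}

# world coordinate arrays (same dims as the grid)
coordArrays <- function(grid) {
    d <- grid@dims
    list(x = array(rep(voxelCoords(grid, 1), times = d[2] * d[3]), d),
         y = array(rep(rep(voxelCoords(grid, 2), each = d[1]),
                       times = d[3]), d),
         z = array(rep(voxelCoords(grid, 3), each = d[1] * d[2]), d))
}

insideEllipseXY <- function(co, center, semi) {
    ((co$x - center[1]) / semi[1])^2 + ((co$y - center[2]) / semi[2])^2 <= 1
}

insideSphere <- function(co, center, r) {
    (co$x - center[1])^2 + (co$y - center[2])^2 + (co$z - center[3])^2 <= r^2
}

insideEllipsoid <- function(co, center, semi) {
    ((co$x - center[1]) / semi[1])^2 + ((co$y - center[2]) / semi[2])^2 +
        ((co$z - center[3]) / semi[3])^2 <= 1
}

#' Generate the planning-CT phantom
#'
#' Builds the piecewise-constant tissue phantom from [phantomParams()], adds
#' Gaussian CT noise (sigma `noiseSigmaHu`), and emits the structure set
#' (BODY, whole_breast_CTV, boost_CTV, heart, lungs). The CTVs are
#' contracted to stay at least `ctvSkinMarginMm` inside the BODY contour.
#' Fully deterministic given `params$seed`.
#'
#' @param params from [phantomParams()]
#' @return `list(pct = ScalarVolume, structures = StructureSet)`
#' @examples
#' ph <- generatePhantom(phantomParams(dims = c(32, 32, 16), seed = 7))
#' ph$structures
#' @export
generatePhantom <- function(params = phantomParams()) {
    grid <- phantomGrid(params)
    co <- coordArrays(grid)
    hu <- params$huTable
    bodyCyl <- insideEllipseXY(co, params$bodyCenterMm, params$bodySemiAxesMm)
    breastSph <- insideSphere(co, params$breastCenterMm, params$breastRadiusMm)
    breast <- breastSph & !bodyCyl
    body <- bodyCyl | breast
    innerBody <- insideEllipseXY(co, params$bodyCenterMm,
                                 params$bodySemiAxesMm - params$adiposeShellMm)
    shell <- bodyCyl & !innerBody
    lungs <- insideEllipsoid(co, params$lungCentersMm[[1]],
                             params$lungSemiAxesMm) |
        insideEllipsoid(co, params$lungCentersMm[[2]], params$lungSemiAxesMm)
    heart <- insideSphere(co, params$heartCenterMm, params$heartRadiusMm) &
        innerBody
    lungs <- lungs & innerBody & !heart # heart displaces lung where they meet
    spine <- ((co$x - params$spineCenterMm[1])^2 +
              (co$y - params$spineCenterMm[2])^2) <= params$spineRadiusMm^2 &
        bodyCyl
    ribs <- array(FALSE, grid@dims)
    ribAngles <- c(-150, -110, -70, 70, 110, 150) * pi / 180
    for (a in ribAngles) {
        cx <- params$bodyCenterMm[1] +
            0.86 * params$bodySemiAxesMm[1] * sin(a)
        cy <- params$bodyCenterMm[2] +
            0.86 * params$bodySemiAxesMm[2] * cos(a)
        ribs <- ribs | (((co$x - cx)^2 + (co$y - cy)^2) <=
                            params$ribRadiusMm^2)
    }
    ribs <- ribs & bodyCyl
    lungs <- lungs & !spine & !ribs # bone displaces lung where they touch
    vals <- array(hu[["air"]], grid@dims)
    vals[bodyCyl] <- hu[["soft"]]
    vals[shell] <- hu[["adipose"]]
    vals[breast] <- hu[["glandular"]]
    vals[lungs] <- hu[["lung"]]
    vals[heart] <- hu[["soft"]]
    vals[spine | ribs] <- hu[["bone"]]
    if (params$noiseSigmaHu > 0) {
        set.seed(params$seed)
        vals <- vals + array(rnorm(length(vals), 0, params$noiseSigmaHu),
                             grid@dims)
    }
    bodyMask <- ROIMask(body, grid, "BODY")
    eroded <- erodeMask(bodyMask, params$ctvSkinMarginMm)
    wbCtv <- breast & eroded@membership
    boost <- insideSphere(co, params$breastCenterMm, params$boostRadiusMm) &
        wbCtv
    structures <- StructureSet(list(
        BODY = bodyMask,
        whole_breast_CTV = ROIMask(wbCtv, grid, "whole_breast_CTV"),
        boost_CTV = ROIMask(boost, grid, "boost_CTV"),
        heart = ROIMask(heart, grid, "heart"),
        lungs = ROIMask(lungs, grid, "lungs")),
        external = "BODY")
    list(pct = ScalarVolume(vals, grid, "HU"), structures = structures,
         grid = grid)
}

#' Specification of the breast surface deformation
#'
#' The anatomical change that triggers a dose evaluation: a smooth outward (swelling) or
#' inward (shrinkage) displacement of the breast surface, modelled as a
#' Gaussian bump of the distance to the breast apex. `peakMm` is the
#' resulting maximum surface displacement; the stored pull-back field is
#' scaled analytically so the tracked surface moves by `peakMm`.
#'
#' @param mode `"swelling"` or `"shrinkage"`
#' @param peakMm peak surface displacement, mm (the modelled inclusion
#'   criterion is a change above 5 mm)
#' @param sigmaMm Gaussian support scale of the bump, mm
#' @return a named list
#' @export
deformationSpec <- function(mode = c("swelling", "shrinkage"), peakMm = 8,
                            sigmaMm = 25) {
    mode <- match.arg(mode)
    stopifnot(peakMm >= 0, sigmaMm > 0)
    list(mode = mode, peakMm = peakMm, sigmaMm = sigmaMm)
}

#' Deform the planning-CT anatomy into the repeat-CT anatomy
#'
#' Applies the breast surface deformation of [deformationSpec()] as a
#' pull-back displacement field (warped(x) = pCT(x + u(x))) and warps the
#' structure set consistently. Errors if the field folds (non-positive
#' Jacobian determinant anywhere).
#'
#' @param pct planning-CT [ScalarVolume-class]
#' @param structures planning-CT [StructureSet-class]
#' @param spec from [deformationSpec()]
#' @param params the [phantomParams()] used to build `pct` (for the breast
#'   geometry that anchors the bump)
#' @return `list(rct, structures, field)` with the ground-truth
#'   [DeformationField-class]
#' @export
applyBreastDeformation <- function(pct, structures, spec,
                                   params = phantomParams()) {
    grid <- pct@grid
    d <- grid@dims
    if (spec$peakMm == 0) {
        field <- DeformationField(array(0, c(d, 3)), grid)
        return(list(rct = pct, structures = structures, field = field))
    }
    bc <- params$breastCenterMm
    bodyC <- c(params$bodyCenterMm, 0)
    nhat <- bc - bodyC
    nhat <- nhat / sqrt(sum(nhat^2))
    anchor <- bc + params$breastRadiusMm * nhat
    # pull-back amplitude giving a forward surface displacement of peakMm
    amp <- spec$peakMm * exp(spec$peakMm^2 / (2 * spec$sigmaMm^2))
    sgn <- if (spec$mode == "swelling") -1 else 1
    co <- coordArrays(grid)
    g <- exp(-((co$x - anchor[1])^2 + (co$y - anchor[2])^2 +
               (co$z - anchor[3])^2) / (2 * spec$sigmaMm^2))
    u <- array(0, c(d, 3))
    for (a in 1:3) u[, , , a] <- sgn * amp * g * nhat[a]
    field <- DeformationField(u, grid)
    jac <- jacobianDeterminant(field)
    if (min(jac@values) <= 0)
        stop("deformation field folds (non-positive Jacobian); ",
             "reduce peakMm or increase sigmaMm")
    rct <- applyTransform(pct, field)
    strRct <- applyTransform(structures, field)
    if (!is.null(params$airPocket)) {
        ap <- params$airPocket
        cav <- insideSphere(co, ap$centerMm, ap$radiusMm)
        v <- rct@values
        v[cav] <- params$huTable[["air"]]
        rct <- ScalarVolume(v, grid, "HU")
    }
    list(rct = rct, structures = strRct, field = field)
}

#' Phenomenological CBCT artifact model
#'
#' Inside a cylindrical field of view the CBCT equals the repeat-CT anatomy
#' passed through a strictly monotone grey-level distortion
#' (`gain * HU + offset`), plus a smooth low-frequency in-plane shading
#' field of the given amplitude and spatial scale, plus Gaussian noise.
#' Outside the FOV the volume is air (-1000).
#'
#' @param gain,offsetHu affine HU-scale distortion (`gain` > 0)
#' @param shadingAmplitudeHu maximum absolute shading inside the FOV
#' @param shadingScaleMm shortest spatial wavelength present in the shading
#' @param noiseSigmaHu CBCT noise standard deviation
#' @param fovRadiusMm,fovLengthMm,fovCenterMm cylindrical FOV (axis along z)
#' @return a named list
#' @export
cbctArtifactModel <- function(gain = 0.9, offsetHu = -30,
                              shadingAmplitudeHu = 80, shadingScaleMm = 100,
                              noiseSigmaHu = 20, fovRadiusMm = 115,
                              fovLengthMm = 120, fovCenterMm = c(25, 25, 0)) {
    stopifnot(gain > 0, fovRadiusMm > 0, fovLengthMm > 0,
              shadingAmplitudeHu >= 0, noiseSigmaHu >= 0, shadingScaleMm > 0)
    list(gain = gain, offsetHu = offsetHu,
         shadingAmplitudeHu = shadingAmplitudeHu,
         shadingScaleMm = shadingScaleMm, noiseSigmaHu = noiseSigmaHu,
         fovRadiusMm = fovRadiusMm, fovLengthMm = fovLengthMm,
         fovCenterMm = fovCenterMm)
}

# smooth in-plane shading field, band-limited at artifact$shadingScaleMm,
# normalised to the requested amplitude over the FOV
shadingField <- function(grid, artifact, fovMask, seed) {
    if (artifact$shadingAmplitudeHu == 0)
        return(array(0, grid@dims))
    d <- grid@dims
    ext <- (d[1:2] - 1) * grid@spacing[1:2]
    Lmax <- pmax(1L, floor(2 * ext / artifact$shadingScaleMm))
    set.seed(seed)
    xs <- (voxelCoords(grid, 1) - grid@origin[1]) / ext[1]
    ys <- (voxelCoords(grid, 2) - grid@origin[2]) / ext[2]
    s2d <- matrix(0, d[1], d[2])
    for (l in 0:Lmax[1]) {
        for (m in 0:Lmax[2]) {
            if (l == 0 && m == 0) next
            cf <- rnorm(1) / (1 + l * l + m * m)
            s2d <- s2d + cf * outer(cos(pi * l * xs), cos(pi * m * ys))
        }
    }
    s <- array(rep(as.numeric(s2d), d[3]), d)
    mx <- max(abs(s[fovMask]))
    if (mx < 1e-12) return(array(0, d))
    s * artifact$shadingAmplitudeHu / mx
}

#' Simulate a CBCT of the repeat-CT anatomy
#'
#' @param rct repeat-CT [ScalarVolume-class]
#' @param artifact from [cbctArtifactModel()]
#' @param seed integer seed for the shading field and noise
#' @return `list(cbct, fovMask, truth)`; `truth` holds the injected shading
#'   field (as a [ScalarVolume-class]) and the distortion parameters, so
#'   downstream correction accuracy is measurable exactly
#' @export
simulateCbct <- function(rct, artifact = cbctArtifactModel(), seed = 1L) {
    grid <- rct@grid
    co <- coordArrays(grid)
    fc <- artifact$fovCenterMm
    fov <- ((co$x - fc[1])^2 + (co$y - fc[2])^2 <= artifact$fovRadiusMm^2) &
        (abs(co$z - fc[3]) <= artifact$fovLengthMm / 2)
    if (!any(fov)) stop("CBCT FOV does not intersect the volume")
    shading <- shadingField(grid, artifact, fov, seed = seed)
    distorted <- artifact$gain * rct@values + artifact$offsetHu
    set.seed(seed + 1L)
    noise <- if (artifact$noiseSigmaHu > 0)
        array(rnorm(prod(grid@dims), 0, artifact$noiseSigmaHu), grid@dims)
    else array(0, grid@dims)
    v <- array(-1000, grid@dims)
    v[fov] <- distorted[fov] + shading[fov] + noise[fov]
    list(cbct = ScalarVolume(v, grid, "HU"),
         fovMask = ROIMask(fov, grid, "FOV"),
         truth = list(shading = ScalarVolume(shading, grid, "HU"),
                      gain = artifact$gain, offsetHu = artifact$offsetHu))
}

#' Generate a complete synthetic study case
#'
#' One complete synthetic case: a planning CT, the deformed repeat-CT
#' anatomy acquired within days of the CBCT, and a CBCT of that anatomy with
#' the full artifact chain, plus every piece of ground truth (deformation
#' field, structure sets, FOV, artifact parameters).
#'
#' @param seed integer seed; all randomness in the case derives from it
#' @param params from [phantomParams()] (its own seed is overridden)
#' @param deform from [deformationSpec()]
#' @param artifact from [cbctArtifactModel()]
#' The planning and repeat CT are two acquisitions of the same patient, so
#' they share the underlying anatomy but carry independent realisations of
#' the CT noise (`params$noiseSigmaHu`): the noiseless anatomy is built
#' once, deformed, and each scan then receives its own noise draw.
#'
#' @return a list with elements `pct`, `rct`, `cbct`, `structuresPct`,
#'   `structuresRct`, `field`, `fovMask`, `artifactTruth`, `params`, `seed`
#' @export
generatePhantomCase <- function(seed = 1L, params = phantomParams(),
                                deform = deformationSpec(),
                                artifact = cbctArtifactModel()) {
    seed <- as.integer(seed)
    params$seed <- seed
    clean <- params
    clean$noiseSigmaHu <- 0
    ph <- generatePhantom(clean)
    def <- applyBreastDeformation(ph$pct, ph$structures, deform, clean)
    addNoise <- function(vol, s) {
        if (params$noiseSigmaHu == 0) return(vol)
        set.seed(s)
        ScalarVolume(vol@values +
                         array(rnorm(prod(vol@grid@dims), 0,
                                     params$noiseSigmaHu), vol@grid@dims),
                     vol@grid, "HU")
    }
    pct <- addNoise(ph$pct, seed)
    rct <- addNoise(def$rct, seed + 500L)
    sim <- simulateCbct(rct, artifact, seed = seed + 1000L)
    structure(list(pct = pct, rct = rct, cbct = sim$cbct,
                   structuresPct = ph$structures,
                   structuresRct = def$structures, field = def$field,
                   fovMask = sim$fovMask, artifactTruth = sim$truth,
                   params = params, deform = deform, artifact = artifact,
                   seed = as.integer(seed)),
              class = "phantomCase")
}
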