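test_that("phantom generation is deterministic under its seed", {
    a <- generatePhantom(smallParams(seed = 11))
    b <- generatePhantom(smallParams(seed = 11))
    expect_identical(values(a$pct), values(b$pct))
    c1 <- generatePhantomCase(7, params = smallParams())
    c2 <- generatePhantomCase(7, params = smallParams())
    expect_identical(values(c1$cbct), values(c2$cbct))
    expect_identical(values(c1$rct), values(c2$rct))
})

test_that("a noiseless phantom is exactly piecewise constant at table values", {
    p <- smallParams(noiseSigmaHu = 0)
    ph <- generatePhantom(p)
    vals <- unique(as.numeric(values(ph$pct)))
    expect_true(all(vals %in% unname(p$huTable)))
    # heart is soft tissue
    heart <- membership(getMask(ph$structures, "heart"))
    expect_equal(mean(values(ph$pct)[heart]), p$huTable[["soft"]])
    # lungs at the lung table value
    lungs <- membership(getMask(ph$structures, "lungs"))
    expect_equal(mean(values(ph$pct)[lungs]), p$huTable[["lung"]])
})

test_that("CTVs stay at least the skin margin inside BODY", {
    ph <- generatePhantom(smallParams(noiseSigmaHu = 0))
    body <- getMask(ph$structures, "BODY")
    ctv <- membership(getMask(ph$structures, "whole_breast_CTV"))
    boost <- membership(getMask(ph$structures, "boost_CTV"))
    eroded <- membership(erodeMask(body, 5))
    expect_true(all(eroded | !ctv))  # ctv subset of eroded body
    expect_true(all(ctv | !boost))   # boost subset of whole-breast CTV
    expect_gt(sum(boost), 0)
})

test_that("organs exceeding the grid raise a parameter error", {
    expect_error(phantomParams(dims = c(32, 32, 16), spacingMm = 2.5,
                               seed = 1),
                 "exceeds the grid")
})

test_that("zero-peak deformation is the identity", {
    ph <- generatePhantom(smallParams(noiseSigmaHu = 0))
    def <- applyBreastDeformation(ph$pct, ph$structures,
                                  deformationSpec(peakMm = 0), smallParams())
    expect_identical(values(def$rct), values(ph$pct))
    expect_true(all(displacement(def$field) == 0))
})

test_that("swelling grows and shrinkage shrinks the whole-breast CTV", {
    p <- smallParams(noiseSigmaHu = 0)
    ph <- generatePhantom(p)
    n0 <- voxelCount(getMask(ph$structures, "whole_breast_CTV"))
    sw <- applyBreastDeformation(ph$pct, ph$structures,
                                 deformationSpec("swelling", peakMm = 8), p)
    sh <- applyBreastDeformation(ph$pct, ph$structures,
                                 deformationSpec("shrinkage", peakMm = 8), p)
    expect_gt(voxelCount(getMask(sw$structures, "whole_breast_CTV")), n0)
    expect_lt(voxelCount(getMask(sh$structures, "whole_breast_CTV")), n0)
})

test_that("the tracked surface displacement matches the requested peak", {
    # surface-point tracking oracle: along the outward ray through the
    # breast apex, locate the warped and original body boundaries by
    # bisection on mask membership pulled through the known field
    p <- phantomParams(seed = 1, noiseSigmaHu = 0)
    ph <- generatePhantom(p)
    peak <- 8
    def <- applyBreastDeformation(ph$pct, ph$structures,
                                  deformationSpec(peakMm = peak), p)
    bc <- c(p$breastCenterMm[1:2], 0)
    nhat <- c(bc[1:2] - p$bodyCenterMm, 0)
    nhat <- nhat / sqrt(sum(nhat^2))
    anchor <- bc + p$breastRadiusMm * nhat
    inBody <- function(structs, pt) {
        g <- geometry(structs)
        idx <- round((pt - origin(g)) / spacing(g)) + 1
        m <- membership(getMask(structs, "BODY"))
        m[idx[1], idx[2], idx[3]]
    }
    boundary <- function(structs) {
        loT <- -10; hiT <- 15
        for (i in 1:40) {
            mid <- (loT + hiT) / 2
            if (inBody(structs, anchor + mid * nhat)) loT <- mid else hiT <- mid
        }
        (loT + hiT) / 2
    }
    shift <- boundary(def$structures) - boundary(ph$structures)
    expect_lt(abs(shift - peak), 0.4 + max(spacing(geometry(ph$pct))) / 2)
})

test_that("the deformation field does not fold", {
    p <- smallParams(noiseSigmaHu = 0)
    ph <- generatePhantom(p)
    def <- applyBreastDeformation(ph$pct, ph$structures,
                                  deformationSpec(peakMm = 8), p)
    jac <- jacobianDeterminant(def$field)
    expect_gt(min(values(jac)), 0)
    # a folding field is rejected
    expect_error(applyBreastDeformation(ph$pct, ph$structures,
                                        deformationSpec(peakMm = 60,
                                                        sigmaMm = 12), p),
                 "folds")
})

test_that("an artifact-free CBCT equals the repeat CT inside the FOV", {
    p <- smallParams(noiseSigmaHu = 0)
    ph <- generatePhantom(p)
    art <- cbctArtifactModel(gain = 1, offsetHu = 0, shadingAmplitudeHu = 0,
                             noiseSigmaHu = 0)
    sim <- simulateCbct(ph$pct, art, seed = 1)
    fov <- membership(sim$fovMask)
    expect_identical(values(sim$cbct)[fov], values(ph$pct)[fov])
    expect_true(all(values(sim$cbct)[!fov] == -1000))
})

test_that("the affine grey-level distortion is applied exactly", {
    v <- constVolume(40, dims = c(12L, 12L, 6L), spacing = 10)
    art <- cbctArtifactModel(gain = 0.9, offsetHu = -30,
                             shadingAmplitudeHu = 0, noiseSigmaHu = 0,
                             fovRadiusMm = 40, fovLengthMm = 40,
                             fovCenterMm = c(55, 55, 25))
    sim <- simulateCbct(v, art, seed = 1)
    fov <- membership(sim$fovMask)
    expect_true(all(abs(values(sim$cbct)[fov] - 6) < 1e-12)) # 0.9*40 - 30
})

test_that("the shading field attains exactly its stated amplitude in the FOV", {
    p <- smallParams(noiseSigmaHu = 0)
    ph <- generatePhantom(p)
    art <- cbctArtifactModel(gain = 1, offsetHu = 0, shadingAmplitudeHu = 80,
                             noiseSigmaHu = 0)
    sim <- simulateCbct(ph$pct, art, seed = 5)
    fov <- membership(sim$fovMask)
    resid <- values(sim$cbct)[fov] - values(ph$pct)[fov]
    expect_lt(abs(max(abs(resid)) - 80), 1e-6)
    # and matches the returned ground-truth field voxel for voxel
    expect_lt(max(abs(resid - values(sim$truth$shading)[fov])), 1e-9)
})
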