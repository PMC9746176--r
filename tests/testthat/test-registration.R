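test_that("self rigid registration returns the identity", {
    ph <- generatePhantom(smallParams(seed = 3))
    tf <- registerRigid(ph$pct, ph$pct)
    expect_lt(max(abs(tf@translation)), 0.1)
    expect_lt(max(abs(tf@rotation)), 0.1)
})

test_that("a known translation is recovered within 0.5 mm", {
    ph <- generatePhantom(smallParams(seed = 3))
    fixed <- ph$pct
    g <- geometry(fixed)
    shift <- c(4, -6, 2)
    # shift the volume by moving its grid origin: no interpolation involved
    moving <- ScalarVolume(values(fixed),
                           ImageGrid(gridDim(g), spacing(g),
                                     origin(g) + shift), "HU")
    tf <- registerRigid(fixed, moving)
    # pull-back convention: sampling moving at x + shift aligns it with fixed
    expect_lt(max(abs(tf@translation - shift)), 0.5)
    expect_lt(max(abs(tf@rotation)), 0.3)
})

test_that("a known 3-degree axial rotation is recovered within 0.3 degrees", {
    ph <- generatePhantom(smallParams(seed = 3, noiseSigmaHu = 0))
    fixed <- ph$pct
    g <- geometry(fixed)
    ctr <- origin(g) + (gridDim(g) - 1) * spacing(g) / 2
    moving <- applyTransform(fixed,
                             RigidTransform(rotation = c(0, 0, 3),
                                            center = ctr))
    tf <- registerRigid(fixed, moving)
    expect_lt(abs(tf@rotation[3] - (-3)), 0.3)
    # the rot3 mode constrains translations to zero
    tf3 <- registerRigid(fixed, moving, dof = "rot3")
    expect_identical(tf3@translation, c(0, 0, 0))
    expect_lt(abs(tf3@rotation[3] - (-3)), 0.3)
})

test_that("the registration objective never exceeds its identity value", {
    ph <- generatePhantom(smallParams(seed = 4))
    ph2 <- generatePhantom(smallParams(seed = 5))
    fixed <- ph$pct
    moving <- ph2$pct # different noise realisation, same anatomy
    tf <- registerRigid(fixed, moving)
    g <- geometry(fixed)
    ctr <- origin(g) + (gridDim(g) - 1) * spacing(g) / 2
    # evaluate the registration objective itself: the border-cropped metric
    # (the 15 mm rind is excluded so out-of-extent fill cannot dominate)
    mk <- array(TRUE, gridDim(g))
    nb <- ceiling(15 / spacing(g))
    d <- gridDim(g)
    mk[c(1:nb[1], d[1] - 0:(nb[1] - 1)), , ] <- FALSE
    mk[, c(1:nb[2], d[2] - 0:(nb[2] - 1)), ] <- FALSE
    mk[, , c(1:nb[3], d[3] - 0:(nb[3] - 1))] <- FALSE
    costAt <- function(par) cbctdose:::rigidCost(
        par, values(fixed), g, moving, ctr, mk)
    expect_lte(costAt(c(tf@rotation, tf@translation)), costAt(rep(0, 6)))
    # non-overlapping volumes are rejected
    far <- ScalarVolume(values(moving),
                        ImageGrid(gridDim(geometry(moving)),
                                  spacing(geometry(moving)),
                                  origin(geometry(moving)) + 1000), "HU")
    expect_error(registerRigid(fixed, far), "overlap")
})

test_that("warping with a zero field is the identity", {
    ph <- generatePhantom(smallParams(seed = 3))
    g <- geometry(ph$pct)
    zero <- DeformationField(array(0, c(gridDim(g), 3)), g)
    w <- applyTransform(ph$pct, zero)
    expect_identical(values(w), values(ph$pct))
})

test_that("a constant displacement shifts an affine field by the closed form", {
    g <- ImageGrid(c(12L, 12L, 12L), spacing = 2)
    x <- voxelCoords(g, 1)
    z <- voxelCoords(g, 3)
    ramp <- ScalarVolume(array(rep(z, each = 144), c(12, 12, 12)), g)
    u <- array(0, c(12, 12, 12, 3))
    u[, , , 3] <- 5 # sample 5 mm up in z
    w <- applyTransform(ramp, DeformationField(u, g))
    interior <- values(w)[, , 1:9]
    expected <- array(rep(z + 5, each = 144), c(12, 12, 12))[, , 1:9]
    expect_lt(max(abs(interior - expected)), 1e-9)
})

test_that("warping a ball mask through a diffeomorphic field keeps it connected", {
    p <- smallParams(noiseSigmaHu = 0)
    ph <- generatePhantom(p)
    def <- applyBreastDeformation(ph$pct, ph$structures,
                                  deformationSpec(peakMm = 8), p)
    heart <- applyTransform(getMask(ph$structures, "heart"), def$field)
    g <- geometry(heart)
    lab <- cbctdose:::cpp_label3d(as.logical(membership(heart)), gridDim(g))
    expect_equal(max(lab), 1) # one connected component
})

test_that("self deformable registration returns a near-zero field", {
    ph <- generatePhantom(smallParams(seed = 3))
    fld <- registerDeformable(ph$pct, ph$pct)
    mag <- sqrt(apply(displacement(fld)^2, 1:3, sum))
    expect_lt(max(mag), 0.2)
})

test_that("demons recovers a known smooth deformation", {
    p <- smallParams(noiseSigmaHu = 0)
    ph <- generatePhantom(p)
    def <- applyBreastDeformation(ph$pct, ph$structures,
                                  deformationSpec(peakMm = 8), p)
    fld <- suppressWarnings(registerDeformable(def$rct, ph$pct))
    tru <- displacement(def$field)
    err <- sqrt(apply((displacement(fld) - tru)^2, 1:3, sum))
    moving <- sqrt(apply(tru^2, 1:3, sum)) > 1
    expect_lt(mean(err[moving]), 2)
    # warping with the recovered field reduces the MSE by at least 80%
    w <- applyTransform(ph$pct, fld)
    mse0 <- mean((values(def$rct) - values(ph$pct))^2)
    mse1 <- mean((values(def$rct) - values(w))^2)
    expect_lt(mse1, 0.2 * mse0)
})

test_that("the focus mask zeroes the field outside its dilation", {
    p <- smallParams(noiseSigmaHu = 0)
    ph <- generatePhantom(p)
    def <- applyBreastDeformation(ph$pct, ph$structures,
                                  deformationSpec(peakMm = 8), p)
    focus <- getMask(def$structures, "whole_breast_CTV")
    fld <- suppressWarnings(
        registerDeformable(def$rct, ph$pct, focusMask = focus,
                           focusDilationMm = 15))
    outside <- !membership(dilateMask(focus, 15))
    mag <- sqrt(apply(displacement(fld)^2, 1:3, sum))
    expect_true(all(mag[outside] == 0))
})
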