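test_that("NIfTI round trip preserves values and grid metadata bit-exactly", {
    set.seed(1)
    g <- ImageGrid(c(8L, 8L, 8L), spacing = c(1, 1, 3),
                   origin = c(-10, 5, 2.5))
    v <- ScalarVolume(array(rnorm(512), c(8, 8, 8)), g)
    path <- tempfile(fileext = ".nii.gz")
    writeVolume(v, path)
    r <- readVolume(path)
    expect_identical(values(r), values(v))
    expect_equal(spacing(r), c(1, 1, 3))
    expect_equal(origin(r), c(-10, 5, 2.5))
})

test_that("NRRD round trip preserves values and grid metadata", {
    set.seed(2)
    g <- ImageGrid(c(6L, 5L, 4L), spacing = c(2, 2.5, 3), origin = c(1, 2, 3))
    v <- ScalarVolume(array(rnorm(120), c(6, 5, 4)), g)
    path <- tempfile(fileext = ".nrrd")
    writeVolume(v, path)
    r <- readVolume(path)
    expect_identical(values(r), values(v))
    expect_equal(spacing(r), c(2, 2.5, 3))
    expect_equal(origin(r), c(1, 2, 3))
})

test_that("unreadable and truncated volume files raise informative errors", {
    expect_error(readVolume("/nonexistent/vol.nii.gz"), "no such file")
    # truncated NRRD: header promises more data than present
    path <- tempfile(fileext = ".nrrd")
    v <- constVolume(0, dims = c(4L, 4L, 4L))
    writeVolume(v, path)
    bytes <- readBin(path, "raw", file.size(path))
    writeBin(bytes[1:(length(bytes) - 100)], path)
    expect_error(readVolume(path), "truncated")
    unknown <- tempfile(fileext = ".xyz")
    writeBin(raw(10), unknown)
    expect_error(readVolume(unknown), "format")
})

test_that("structure sets round-trip through a mask directory", {
    m1 <- ballMask(20, dims = c(17L, 17L, 9L), spacing = 4, name = "BODY")
    m2 <- ballMask(10, dims = c(17L, 17L, 9L), spacing = 4, name = "heart")
    ss <- StructureSet(list(BODY = m1, heart = m2), external = "BODY")
    dir <- tempfile()
    writeStructureSet(ss, dir)
    r <- readStructureSet(dir)
    expect_identical(roiNames(r), c("BODY", "heart"))
    expect_identical(externalName(r), "BODY")
    expect_identical(membership(getMask(r, "heart")), membership(m2))
})

test_that("resampling is the identity on the source grid and preserves constants", {
    set.seed(3)
    g <- ImageGrid(c(10L, 9L, 8L), spacing = c(2, 2, 2.5))
    v <- ScalarVolume(array(rnorm(720), c(10, 9, 8)), g)
    r <- resampleToGrid(v, g)
    expect_lt(max(abs(values(r) - values(v))), 1e-9)
    # nearest is idempotent on its own grid
    rn <- resampleToGrid(v, g, "nearest")
    expect_identical(values(rn), values(v))
    # constant volume stays constant inside the source extent
    cv <- constVolume(100, dims = c(8L, 8L, 8L), spacing = 2)
    tg <- ImageGrid(c(5L, 5L, 5L), spacing = 2, origin = c(1, 1, 1))
    rc <- resampleToGrid(cv, tg)
    expect_true(all(values(rc) == 100))
})

test_that("trilinear resampling reproduces an affine field exactly", {
    g <- ImageGrid(c(9L, 9L, 9L), spacing = 2)
    x <- voxelCoords(g, 1)
    ramp <- ScalarVolume(array(rep(x, 81), c(9, 9, 9)), g)
    half <- ImageGrid(c(15L, 15L, 15L), spacing = 1, origin = c(0.5, 0.5, 0.5))
    r <- resampleToGrid(ramp, half)
    expected <- array(rep(voxelCoords(half, 1), 225), c(15, 15, 15))
    expect_lt(max(abs(values(r) - expected)), 1e-6)
})

test_that("resampling to a non-overlapping grid errors", {
    v <- constVolume(0, dims = c(4L, 4L, 4L))
    far <- ImageGrid(c(4L, 4L, 4L), origin = c(100, 100, 100))
    expect_error(resampleToGrid(v, far), "overlap")
})

test_that("erosion follows world-space Euclidean distance", {
    ball <- ballMask(30)
    expect_identical(membership(erodeMask(ball, 0)), membership(ball))
    er <- erodeMask(ball, 20)
    # brute-force oracle: distance from each kept voxel to the complement
    g <- geometry(ball)
    out <- which(!membership(ball), arr.ind = TRUE)
    outW <- cbind(voxelCoords(g, 1)[out[, 1]], voxelCoords(g, 2)[out[, 2]],
                  voxelCoords(g, 3)[out[, 3]])
    kept <- which(membership(er), arr.ind = TRUE)
    keptW <- cbind(voxelCoords(g, 1)[kept[, 1]], voxelCoords(g, 2)[kept[, 2]],
                   voxelCoords(g, 3)[kept[, 3]])
    minD <- vapply(seq_len(nrow(keptW)), function(i)
        sqrt(min(colSums((t(outW) - keptW[i, ])^2))), numeric(1))
    expect_true(all(minD > 20))
    # result is a ball of radius ~10 (one-voxel boundary tolerance)
    ref <- ballMask(10)
    disagree <- xor(membership(er), membership(ref))
    # disagreement confined to the boundary shell
    r2 <- with(list(g = g), {
        x <- voxelCoords(g, 1); y <- voxelCoords(g, 2); z <- voxelCoords(g, 3)
        outer(outer(x^2, y^2, "+"), z^2, "+")
    })
    expect_true(all(abs(sqrt(r2[disagree]) - 10) <= max(spacing(g)) * 2))
    expect_equal(voxelCount(erodeMask(ballMask(10), 20)), 0)
})

test_that("erosion is monotone in the margin and preserves the grid", {
    ball <- ballMask(25)
    margins <- c(0, 4, 8, 12, 16)
    prev <- membership(ball)
    for (m in margins) {
        cur <- membership(erodeMask(ball, m))
        expect_true(all(prev | !cur)) # cur subset of prev
        prev <- cur
    }
    expect_error(erodeMask(ball, -1), ">= 0")
})

test_that("in-plane erosion never removes along the z axis", {
    g <- ImageGrid(c(21L, 21L, 9L), spacing = c(2, 2, 2),
                   origin = c(-20, -20, -8))
    x <- voxelCoords(g, 1)
    # finite cylinder: occupies z slices 3..7 only, so its flat faces are
    # inside the grid and 3-D erosion can eat them
    cyl <- outer(outer(x^2, x^2, "+"),
                 ifelse(seq_len(9) %in% 3:7, 0, Inf), "+") <= 15^2
    m <- ROIMask(cyl, g, "cyl")
    er <- erodeMask(m, 6, inPlaneOnly = TRUE)
    # in-plane mode keeps every occupied z slice
    expect_identical(membership(er)[, , 3], membership(er)[, , 5])
    expect_equal(sum(membership(er)[, , 3]), sum(membership(er)[, , 7]))
    er3 <- erodeMask(m, 6)
    expect_lt(voxelCount(er3), voxelCount(er))
})

test_that("mask intersection matches an exhaustive voxel scan", {
    a <- ballMask(25)
    g <- geometry(a)
    x <- voxelCoords(g, 1)
    boxArr <- array(FALSE, gridDim(g))
    boxArr[x > -10, , ] <- TRUE
    b <- ROIMask(boxArr, g, "box")
    i <- intersectMasks(a, b)
    expect_identical(membership(i), membership(a) & membership(b))
    expect_lte(voxelCount(i), min(voxelCount(a), voxelCount(b)))
    # idempotence and absorbing element
    expect_identical(membership(intersectMasks(a, a)), membership(a))
    empty <- ROIMask(array(FALSE, gridDim(g)), g, "empty")
    expect_equal(voxelCount(intersectMasks(a, empty)), 0)
    # grid mismatch instructs to resample
    other <- ballMask(10, dims = c(9L, 9L, 9L), spacing = 2)
    expect_error(intersectMasks(a, other), "resample")
})

test_that("rigid transforms invert to numerical identity", {
    tf <- RigidTransform(rotation = c(10, -5, 30), translation = c(4, -6, 2),
                         center = c(1, 2, 3))
    inv <- invertRigid(tf)
    # composite pull-back maps points back to themselves
    R1 <- cbctdose:::eulerMatrix(tf@rotation)
    R2 <- cbctdose:::eulerMatrix(inv@rotation)
    p <- c(17, -23, 9)
    q <- as.numeric(R1 %*% (p - tf@center)) + tf@center + tf@translation
    back <- as.numeric(R2 %*% (q - inv@center)) + inv@center + inv@translation
    expect_lt(max(abs(back - p)), 1e-9)
})

test_that("class validity catches malformed objects", {
    expect_error(ImageGrid(c(4, 4, 4), spacing = c(1, -1, 1)), "positive")
    expect_error(ScalarVolume(array(NA_real_, c(2, 2, 2)), quantity = "HU"),
                 "finite")
    expect_error(ScalarVolume(array(-1, c(2, 2, 2)), quantity = "dose"),
                 ">= 0")
    m <- ballMask(5, dims = c(5L, 5L, 5L))
    expect_error(StructureSet(list(A = m), external = "BODY"), "external")
})
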