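# six-plateau block phantom: one representative HU per density class
plateauPhantom <- function(noiseSigmaHu = 0, seed = 1,
                           hu = c(-1000, -750, -90, 40, 700, 2200)) {
    dims <- c(24L, 24L, 12L)
    g <- ImageGrid(dims, spacing = 4)
    v <- array(hu[1], dims)
    truth <- array(1L, dims)
    for (k in 2:6) {
        sel <- seq.int(4 * (k - 1) + 1, 4 * k)
        v[sel, , ] <- hu[k]
        truth[sel, , ] <- k
    }
    if (noiseSigmaHu > 0) {
        set.seed(seed)
        v <- v + array(rnorm(prod(dims), 0, noiseSigmaHu), dims)
    }
    list(vol = ScalarVolume(v, g, "HU"),
         body = ROIMask(array(TRUE, dims), g, "BODY"), truth = truth)
}

test_that("multilevel Otsu classifies a noiseless six-plateau phantom perfectly", {
    ph <- plateauPhantom()
    corr <- correctHuOverride(ph$vol, ph$body)
    expect_identical(correctionMethod(corr), "CBCT_HU")
    cls <- as.integer(values(corr@classes))
    expect_equal(mean(cls == as.integer(ph$truth)), 1)
    # class -> density mapping: a lung-class voxel carries 0.26 g/cm^3
    dens <- densityVolume(corr)
    expect_true(all(values(dens)[ph$truth == 2L] == 0.26))
    expect_true(all(values(dens)[ph$truth == 1L] == 0.00121))
    # raw grey levels are retained unaltered
    expect_identical(values(huVolume(corr)), values(ph$vol))
})

test_that("thresholds are strictly increasing and classification is a partition", {
    ph <- plateauPhantom(noiseSigmaHu = 30)
    corr <- correctHuOverride(ph$vol, ph$body)
    thr <- corr@provenance$thresholds
    expect_length(thr, 5)
    expect_true(all(diff(thr) > 0))
    cls <- as.integer(values(corr@classes))
    expect_true(all(cls %in% 1:6))
})

test_that("a constant image cannot be multilevel-thresholded", {
    v <- constVolume(40, dims = c(8L, 8L, 8L))
    body <- ROIMask(array(TRUE, c(8, 8, 8)), geometry(v), "BODY")
    expect_error(correctHuOverride(v, body), "distinct grey levels")
})

test_that("the identity pair yields an identity conversion within one bin", {
    ph <- generatePhantom(smallParams(seed = 6))
    mask <- getMask(ph$structures, "BODY")
    conv <- estimateConversion(ph$pct, ph$pct, mask)
    binW <- diff(range(conv@x)) / (length(conv@x) - 1) *
        (length(conv@x) / 64) # conservative: observed anchor span per bin
    xs <- seq(min(conv@x), max(conv@x), length.out = 200)
    expect_lt(max(abs(applyConversion(conv, xs) - xs)),
              diff(quantile(values(ph$pct)[membership(mask)],
                            c(0.01, 0.99))) / 64 + 1e-9)
})

test_that("an affine grey-level distortion is inverted at the tissue plateaus", {
    p <- smallParams(noiseSigmaHu = 0)
    ph <- generatePhantom(p)
    distorted <- ScalarVolume(0.9 * values(ph$pct) - 30, geometry(ph$pct),
                              "HU")
    mask <- getMask(ph$structures, "BODY")
    conv <- estimateConversion(distorted, ph$pct, mask)
    binW <- diff(quantile(values(distorted)[membership(mask)],
                          c(0.01, 0.99))) / 64
    for (h in c(-90, 20, 40, 700)) # plateaus well inside the masked range
        expect_lt(abs(applyConversion(conv, 0.9 * h - 30) - h), binW)
})

test_that("conversion estimation rejects degenerate input", {
    v <- constVolume(0, dims = c(8L, 8L, 8L))
    g <- geometry(v)
    empty <- ROIMask(array(FALSE, c(8, 8, 8)), g, "empty")
    full <- ROIMask(array(TRUE, c(8, 8, 8)), g, "full")
    expect_error(estimateConversion(v, v, empty), "empty")
    expect_error(estimateConversion(v, v, full), "degenerate")
})

test_that("conversion anchors are monotone by construction", {
    case <- generatePhantomCase(9, params = smallParams())
    conv <- estimateConversion(case$cbct, case$rct, case$fovMask)
    expect_true(all(diff(conv@x) > 0))
    expect_true(all(diff(conv@y) >= -1e-9))
})

test_that("analytical correction with nothing to correct stays near the repeat CT", {
    p <- smallParams(noiseSigmaHu = 5)
    case <- generatePhantomCase(4, params = p,
                                artifact = cbctArtifactModel(
                                    gain = 1, offsetHu = 0,
                                    shadingAmplitudeHu = 0, noiseSigmaHu = 5))
    body <- getMask(case$structuresRct, "BODY")
    cc <- correctAnalytical(case$cbct, case$pct, body, case$fovMask,
                            field = case$field)
    roi <- buildCbctRoi(case$fovMask, body)
    expect_lt(computeMAE(case$rct, huVolume(cc), roi), 2 * (5 + 5))
})

test_that("zero iterations return the input CBCT unchanged", {
    case <- generatePhantomCase(4, params = smallParams())
    body <- getMask(case$structuresRct, "BODY")
    cc <- correctAnalytical(case$cbct, case$pct, body, case$fovMask,
                            field = case$field, nIter = 0L)
    expect_identical(values(huVolume(cc)), values(case$cbct))
})

test_that("accepted analytical iterations never increase the masked MAE", {
    case <- generatePhantomCase(5, params = smallParams())
    body <- getMask(case$structuresRct, "BODY")
    cc <- correctAnalytical(case$cbct, case$pct, body, case$fovMask,
                            field = case$field, nIter = 4L)
    tr <- cc@provenance$maeTrace
    acc <- tr[seq_len(cc@provenance$iterations)]
    expect_true(all(diff(acc) <= 1e-9))
})

test_that("air pocket detection finds an injected cavity and nothing else", {
    p <- smallParams(noiseSigmaHu = 0,
                     airPocket = list(centerMm = c(40, 55, 0),
                                      radiusMm = 8)) # ~2.1 cc
    case <- generatePhantomCase(2, params = p)
    body <- getMask(case$structuresRct, "BODY")
    pockets <- detectAirPockets(case$rct, body)
    g <- geometry(case$rct)
    co <- cbctdose:::coordArrays(g)
    cav <- (co$x - 40)^2 + (co$y - 55)^2 + co$z^2 <= 8^2
    cav <- cav & membership(body)
    expect_gt(sum(membership(pockets) & cav) / sum(cav), 0.9)
    # an all-soft-tissue body has no sub-threshold voxels: empty mask
    soft <- constVolume(40, dims = c(10L, 10L, 10L))
    full <- ROIMask(array(TRUE, c(10, 10, 10)), geometry(soft), "BODY")
    expect_equal(voxelCount(detectAirPockets(soft, full)), 0)
})

test_that("small components below the volume cut are discarded", {
    v <- constVolume(40, dims = c(12L, 12L, 12L), spacing = 5)
    a <- values(v)
    a[3, 3, 3] <- -1000           # single voxel: 0.125 cc < 0.5 cc
    a[7:9, 7:9, 7:9] <- -1000     # 27 voxels: 3.4 cc
    v <- ScalarVolume(a, geometry(v), "HU")
    body <- ROIMask(array(TRUE, c(12, 12, 12)), geometry(v), "BODY")
    pockets <- detectAirPockets(v, body)
    expect_false(membership(pockets)[3, 3, 3])
    expect_true(all(membership(pockets)[7:9, 7:9, 7:9]))
})

test_that("the virtual CT equals the warped planning CT outside air pockets", {
    case <- generatePhantomCase(3, params = smallParams())
    body <- getMask(case$structuresRct, "BODY")
    cc <- correctAnalytical(case$cbct, case$pct, body, case$fovMask,
                            field = case$field)
    vct <- buildVirtualCt(case$pct, cc, case$field, body)
    warped <- applyTransform(case$pct, case$field)
    pockets <- vct@provenance$pockets
    outside <- !membership(pockets)
    expect_identical(values(huVolume(vct))[outside], values(warped)[outside])
})

test_that("air cavities present in only one image are replaced from the corrected CBCT", {
    # cavity exists in the CBCT anatomy (repeat CT) but not the planning CT
    p <- smallParams(noiseSigmaHu = 0,
                     airPocket = list(centerMm = c(40, 55, 0), radiusMm = 8))
    case <- generatePhantomCase(6, params = p,
                                artifact = cbctArtifactModel(noiseSigmaHu = 0))
    body <- getMask(case$structuresRct, "BODY")
    cc <- correctAnalytical(case$cbct, case$pct, body, case$fovMask,
                            field = case$field)
    vct <- buildVirtualCt(case$pct, cc, case$field, body)
    cav <- detectAirPockets(cc@hu, body)
    expect_gt(voxelCount(cav), 0)
    inCav <- membership(cav)
    expect_identical(values(huVolume(vct))[inCav], values(cc@hu)[inCav])
    # cavity only in the planning CT: those voxels are also replaced
    p2 <- smallParams(noiseSigmaHu = 0)
    ph <- generatePhantom(p2)
    g <- geometry(ph$pct)
    co <- cbctdose:::coordArrays(g)
    a <- values(ph$pct)
    a[(co$x - 40)^2 + (co$y - 55)^2 + co$z^2 <= 8^2] <- -1000
    pctCav <- ScalarVolume(a, g, "HU")
    case2 <- generatePhantomCase(6, params = p2,
                                 artifact = cbctArtifactModel(noiseSigmaHu = 0))
    body2 <- getMask(case2$structuresRct, "BODY")
    cc2 <- correctAnalytical(case2$cbct, pctCav, body2, case2$fovMask,
                             field = case2$field)
    vct2 <- buildVirtualCt(pctCav, cc2, case2$field, body2)
    warpedCav <- detectAirPockets(applyTransform(pctCav, case2$field), body2)
    expect_gt(voxelCount(warpedCav), 0)
    m <- membership(warpedCav)
    expect_identical(values(huVolume(vct2))[m], values(cc2@hu)[m])
    # the corrected CBCT is mandatory
    expect_error(buildVirtualCt(ph$pct, NULL, case2$field, body2),
                 "CBCT_CC")
})
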