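singleBeamMatrix <- function(src, iso, sad, halfU = 60, halfV = 60,
                             weight = 1) {
    axis <- (iso - src) / sqrt(sum((iso - src)^2))
    vhat <- c(0, 0, 1)
    uhat <- c(vhat[2] * axis[3] - vhat[3] * axis[2],
              vhat[3] * axis[1] - vhat[1] * axis[3],
              vhat[1] * axis[2] - vhat[2] * axis[1])
    uhat <- uhat / sqrt(sum(uhat^2))
    matrix(c(src, axis, uhat, vhat, -halfU, halfU, -halfV, halfV, weight),
           nrow = 1)
}

test_that("HU-to-density conversion hits its anchors and interpolates", {
    tb <- huDensityTable()
    v <- ScalarVolume(array(c(-1000, 0, 500, 5000), c(4, 1, 1)),
                      ImageGrid(c(4L, 1L, 1L)))
    d <- huToDensity(v, tb)
    expect_equal(as.numeric(values(d)), c(0.00121, 1.0, 1.3, 3.0))
    expect_error(huDensityTable(hu = c(0, -10), density = c(1, 2)))
})

test_that("density outside the FOV is overridden to water inside BODY only", {
    g <- ImageGrid(c(4L, 4L, 4L))
    dens <- ScalarVolume(array(0.3, c(4, 4, 4)), g, "density")
    body <- ROIMask(array(rep(c(TRUE, FALSE), each = 32), c(4, 4, 4)), g,
                    "BODY")
    fov <- ROIMask(array(rep(c(TRUE, FALSE), 32), c(4, 4, 4)), g, "FOV")
    out <- overrideOutsideFov(dens, body, fov)
    tgt <- membership(body) & !membership(fov)
    expect_true(all(values(out)[tgt] == 1.0))
    expect_true(all(values(out)[!tgt] == 0.3))
    # FOV covering BODY changes nothing
    full <- ROIMask(array(TRUE, c(4, 4, 4)), g, "FOV")
    expect_identical(values(overrideOutsideFov(dens, body, full)),
                     values(dens))
})

test_that("the Siddon path agrees with dense-sampling line integrals", {
    set.seed(7)
    g <- ImageGrid(c(16L, 16L, 16L), spacing = c(2, 2.5, 3))
    dens <- ScalarVolume(array(runif(4096, 0, 2), c(16, 16, 16)), g,
                         "density")
    denseIntegral <- function(src, dst, n = 40000) {
        t <- (seq_len(n) - 0.5) / n
        pts <- outer(t, dst - src) + rep(src, each = n)
        idx <- sweep(sweep(pts, 2, origin(g)), 2, spacing(g), "/")
        v <- values(dens)
        acc <- 0
        L <- sqrt(sum((dst - src)^2))
        inb <- idx[, 1] >= -0.5 & idx[, 1] <= 15.5 &
            idx[, 2] >= -0.5 & idx[, 2] <= 15.5 &
            idx[, 3] >= -0.5 & idx[, 3] <= 15.5
        ii <- pmin(pmax(round(idx), 0), 15) + 1
        sel <- which(inb)
        for (s in sel) acc <- acc + v[ii[s, 1], ii[s, 2], ii[s, 3]]
        acc * L / n / 10
    }
    for (i in 1:10) {
        src <- runif(3, -60, -20)
        dst <- runif(3, 10, 40)
        exact <- radiologicalPath(dens, src, dst)
        brute <- denseIntegral(src, dst)
        expect_lt(abs(exact - brute) / max(brute, 1e-6), 0.005)
    }
})

test_that("central-axis dose follows the attenuation and inverse-square law", {
    g <- ImageGrid(c(21L, 21L, 21L), spacing = 5,
                   origin = c(-50, -50, -50))
    water <- ScalarVolume(array(1, c(21, 21, 21)), g, "density")
    sad <- 1000
    src <- c(0, sad, 0)
    beams <- singleBeamMatrix(src, iso = c(0, 0, 0), sad = sad)
    muEff <- 0.05
    raw <- cbctdose:::cpp_dose_siddon(as.numeric(values(water)), c(21L, 21L, 21L),
                                      spacing(g), origin(g), beams, muEff,
                                      4, sad)
    dose <- array(raw, c(21, 21, 21))
    # central axis: x = 0 (i = 11), z = 0 (k = 11); depth grows as y falls
    y <- voxelCoords(g, 2)
    j1 <- 9; j2 <- 15 # two points at depths below the surface
    d1 <- 50 + 2.5 - y[j2]; d2 <- 50 + 2.5 - y[j1] # radiological depth, mm
    r1 <- sad - y[j2]; r2 <- sad - y[j1]
    expected <- exp(-muEff * (d2 - d1) / 10) * (r1 / r2)^2
    measured <- dose[11, j1, 11] / dose[11, j2, 11]
    expect_lt(abs(measured / expected - 1), 0.01)
    # the ray-cast engine matches the same closed form
    raw2 <- cbctdose:::cpp_dose_fast(as.numeric(values(water)),
                                     c(21L, 21L, 21L), spacing(g), origin(g),
                                     beams, muEff, 4, sad, 2, 1.25)
    dose2 <- array(raw2, c(21, 21, 21))
    measured2 <- dose2[11, j1, 11] / dose2[11, j2, 11]
    expect_lt(abs(measured2 / expected - 1), 0.01)
})

test_that("dose rises monotonically when all densities are halved", {
    g <- ImageGrid(c(15L, 15L, 15L), spacing = 5, origin = c(-35, -35, -35))
    set.seed(8)
    dens <- ScalarVolume(array(runif(3375, 0.5, 1.5), c(15, 15, 15)), g,
                         "density")
    half <- ScalarVolume(values(dens) / 2, g, "density")
    beams <- singleBeamMatrix(c(0, 1000, 0), c(0, 0, 0), 1000)
    d1 <- cbctdose:::cpp_dose_siddon(as.numeric(values(dens)), gridDim(g),
                                     spacing(g), origin(g), beams, 0.05, 4,
                                     1000)
    d2 <- cbctdose:::cpp_dose_siddon(as.numeric(values(half)), gridDim(g),
                                     spacing(g), origin(g), beams, 0.05, 4,
                                     1000)
    inField <- d1 > 0
    expect_true(all(d2[inField] >= d1[inField]))
})

test_that("plan normalisation and the frozen-plan contract hold exactly", {
    case <- generatePhantomCase(4, params = smallParams())
    dens <- huToDensity(case$pct)
    ctv <- getMask(case$structuresPct, "whole_breast_CTV")
    plan <- finalizePlan(treatmentPlan(), dens, ctv)
    dose <- computeDose(dens, plan)
    expect_lt(abs(mean(values(dose)[membership(ctv)]) / plan@prescription - 1),
              1e-6)
    # bit-identical reproduction on an identical density volume
    again <- computeDose(ScalarVolume(values(dens), geometry(dens),
                                      "density"), plan)
    expect_identical(values(again), values(dose))
    # an unfinalised plan refuses to compute dose
    expect_error(computeDose(dens, treatmentPlan()), "not finalised")
    # a CTV receiving no dose is rejected at finalisation
    farCtv <- ROIMask(array(FALSE, gridDim(geometry(dens))), geometry(dens),
                      "ctv")
    expect_error(finalizePlan(treatmentPlan(), dens, farCtv), "empty")
})

test_that("DVH statistics match the sort-based percentile oracle", {
    g <- ImageGrid(c(10L, 10L, 1L))
    d <- new("DoseVolume", grid = g,
             values = array(as.numeric(1:100), c(10, 10, 1)),
             quantity = "dose", provenance = list())
    roi <- ROIMask(array(TRUE, c(10, 10, 1)), g, "roi")
    s <- dvhStats(d, roi, prescription = 50)
    expect_equal(s$D95, 5.95)
    expect_equal(s$Dmean, 50.5)
    # oracle: quantile type 7 at 1 - x/100
    for (x in c(1, 2, 95, 98, 99))
        expect_equal(s[[paste0("D", x)]],
                     unname(quantile(as.numeric(1:100), 1 - x / 100,
                                     type = 7)))
    # uniform dose: every statistic equals the dose value
    u <- new("DoseVolume", grid = g, values = array(42.56, c(10, 10, 1)),
             quantity = "dose", provenance = list())
    su <- dvhStats(u, roi, 42.56)
    expect_true(all(abs(unlist(su[c("D1", "D2", "D95", "D98", "D99",
                                    "Dmean")]) - 42.56) < 1e-12))
    expect_equal(su$Dmean_pct, 100)
    expect_error(dvhStats(d, ROIMask(array(FALSE, c(10, 10, 1)), g, "e"), 50),
                 "empty")
})

test_that("DVH orderings hold on random dose fields", {
    set.seed(9)
    g <- ImageGrid(c(8L, 8L, 8L))
    roi <- ROIMask(array(runif(512) < 0.5, c(8, 8, 8)), g, "roi")
    for (i in 1:20) {
        d <- new("DoseVolume", grid = g,
                 values = array(runif(512, 0, 60), c(8, 8, 8)),
                 quantity = "dose", provenance = list())
        s <- dvhStats(d, roi, 42.56)
        expect_lte(s$D99, s$D98)
        expect_lte(s$D98, s$D95)
        expect_lte(s$D2, s$D1)
        expect_lte(s$D95, max(values(d)[membership(roi)]))
    }
})

test_that("dose differences are reported relative to the prescription", {
    g <- ImageGrid(c(4L, 4L, 4L))
    roi <- ROIMask(array(TRUE, c(4, 4, 4)), g, "ctv")
    mk <- function(val) dvhStats(
        new("DoseVolume", grid = g, values = array(val, c(4, 4, 4)),
            quantity = "dose", provenance = list()), roi, 42.56)
    ref <- mk(40)
    rep0 <- doseDifferenceReport(ref, list(self = mk(40)), 42.56)
    expect_true(all(rep0$diffPct == 0))
    # 73 cGy below the reference at a 42.56 Gy prescription: -1.7%
    lower <- doseDifferenceReport(ref, list(x = mk(40 - 0.73)), 42.56)
    expect_equal(unique(round(lower$diffPct, 1)), -1.7)
    higher <- doseDifferenceReport(ref, list(x = mk(41)), 42.56)
    expect_true(all(higher$diffPct > 0))
    expect_error(doseDifferenceReport(ref, list(x = mk(40)), 50),
                 "prescription")
})
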