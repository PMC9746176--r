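# Shared fixtures, built in code: a small, fast phantom configuration and a
# few hand-made volumes.

smallParams <- function(seed = 3L, noiseSigmaHu = 8, ...) {
    phantomParams(dims = c(48L, 48L, 24L), spacingMm = 5,
                  noiseSigmaHu = noiseSigmaHu, seed = seed, ...)
}

smallArtifact <- function(...) cbctArtifactModel(...)

# constant-valued volume on a unit grid
constVolume <- function(value, dims = c(8L, 8L, 8L), spacing = 1,
                        quantity = "HU") {
    ScalarVolume(array(value, dims), ImageGrid(dims, spacing), quantity)
}

# solid ball mask with the given radius (mm) about the grid center
ballMask <- function(radiusMm, dims = c(33L, 33L, 33L), spacing = 2,
                     name = "ball") {
    g <- ImageGrid(dims, spacing, origin = -(dims - 1) * spacing / 2)
    x <- voxelCoords(g, 1); y <- voxelCoords(g, 2); z <- voxelCoords(g, 3)
    r2 <- outer(outer(x^2, y^2, "+"), z^2, "+")
    ROIMask(r2 <= radiusMm^2, g, name)
}

# deterministic smooth random dose pair for gamma tests
randomDosePair <- function(seed, dims = c(16L, 16L, 16L), spacing = 2.5) {
    set.seed(seed)
    g <- ImageGrid(dims, spacing)
    base <- array(rnorm(prod(dims)), dims)
    sm <- function(a) {
        v <- gaussianSmooth(ScalarVolume(a, g, "gamma"), sigmaMm = 6)@values
        v <- v - min(v)
        v / max(v)
    }
    ref <- 40 * sm(base)
    ev <- 40 * sm(base + array(rnorm(prod(dims), 0, 0.25), dims))
    # carve exact zeros so the dose > 0 inclusion rule is exercised
    ref[ref < 8] <- 0
    ev[ev < 6] <- 0
    list(ref = ScalarVolume(ref, g, "dose"),
         ev = ScalarVolume(ev, g, "dose"))
}
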