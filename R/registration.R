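downsampleGrid <- function(grid, factor) {
    if (factor == 1) return(grid)
    dims <- pmax(2L, as.integer(ceiling(grid@dims / factor)))
    sp <- grid@spacing * (grid@dims - 1) / pmax(1L, dims - 1L)
    ImageGrid(dims, spacing = sp, origin = grid@origin)
}

rigidCost <- function(par, fixedVals, fixedGrid, moving, center, mask) {
    R <- eulerMatrix(par[1:3])
    # out-of-extent voxels compare against air so that shifting the moving
    # image away from the fixed one is penalised, not rewarded
    res <- cpp_rigid_resample(as.numeric(moving@values), moving@grid@dims,
                              moving@grid@spacing, moving@grid@origin,
                              fixedGrid@dims, fixedGrid@spacing,
                              fixedGrid@origin, R, center, par[4:6], 0L,
                              defaultFill(moving@quantity))
    d <- fixedVals - res
    if (!is.null(mask)) d <- d[mask]
    mean(d * d)
}

#' Rigid registration by multi-resolution mean-squared-difference search
#'
#' Finds the [RigidTransform-class] minimising the masked mean squared HU
#' difference between `fixed` and the resampled `moving`, via Nelder-Mead
#' over a coarse-to-fine pyramid. The returned objective never exceeds its
#' value at the identity (the identity is returned otherwise). The
#' similarity metric assumes both images are on a common grey-level scale.
#'
#' @param fixed,moving [ScalarVolume-class] objects (must overlap in world
#'   space)
#' @param mask optional [ROIMask-class] on the fixed grid restricting the
#'   metric
#' @param dof `"rigid6"` (3 rotations + 3 translations, default) or
#'   `"rot3"` (rotations only)
#' @param levels downsampling factors, coarse to fine
#' @param maxit Nelder-Mead iterations per level
#' @param borderMm the metric ignores voxels closer than this to the fixed
#'   grid boundary, so out-of-extent fill does not bias the optimum
#' @return a [RigidTransform-class] about the fixed-volume center
#' @export
registerRigid <- function(fixed, moving, mask = NULL,
                          dof = c("rigid6", "rot3"), levels = c(4, 2, 1),
                          maxit = 500, borderMm = 15) {
    dof <- match.arg(dof)
    ef <- gridExtent(fixed@grid); em <- gridExtent(moving@grid)
    if (any(ef["hi", ] < em["lo", ]) || any(em["hi", ] < ef["lo", ]))
        stop("fixed and moving volumes do not overlap in world space")
    center <- fixed@grid@origin + (fixed@grid@dims - 1) *
        fixed@grid@spacing / 2
    interior <- function(g) {
        m <- array(TRUE, g@dims)
        nb <- pmin(ceiling(borderMm / g@spacing), floor((g@dims - 1) / 2))
        for (a in 1:3) {
            if (nb[a] < 1) next
            idx <- c(seq_len(nb[a]), g@dims[a] - seq_len(nb[a]) + 1L)
            if (a == 1) m[idx, , ] <- FALSE
            else if (a == 2) m[, idx, ] <- FALSE
            else m[, , idx] <- FALSE
        }
        m
    }
    par <- rep(0, 6)
    for (f in levels) {
        g <- downsampleGrid(fixed@grid, f)
        fv <- resampleToGrid(fixed, g)
        mk <- interior(g)
        if (!is.null(mask))
            mk <- mk & (resampleToGrid(
                ScalarVolume(array(as.numeric(mask@membership),
                                   mask@grid@dims), mask@grid, "label"),
                g, "nearest", fill = 0)@values > 0.5)
        fvv <- fv@values
        cost <- function(p) {
            pp <- p
            if (dof == "rot3") pp <- c(p[1:3], 0, 0, 0)
            rigidCost(pp, fvv, g, moving, center, mk)
        }
        p0 <- if (dof == "rot3") par[1:3] else par
        opt <- optim(p0, cost, method = "Nelder-Mead",
                     control = list(maxit = maxit, reltol = 1e-10,
                                    parscale = rep(c(2, 5),
                                                   c(3, length(p0) - 3))))
        par <- if (dof == "rot3") c(opt$par, 0, 0, 0) else opt$par
    }
    g <- fixed@grid
    mkFine <- interior(g)
    if (!is.null(mask)) mkFine <- mkFine & mask@membership
    idCost <- rigidCost(rep(0, 6), fixed@values, g, moving, center, mkFine)
    finCost <- rigidCost(par, fixed@values, g, moving, center, mkFine)
    if (finCost > idCost) return(RigidTransform(center = center))
    RigidTransform(rotation = par[1:3], translation = par[4:6],
                   center = center)
}

#' Deformable registration (multi-resolution demons)
#'
#' Thirion-style demons with Gaussian field regularisation over a
#' coarse-to-fine pyramid, returning a smooth pull-back
#' [DeformationField-class] on the fixed grid such that warping `moving`
#' with it approximates `fixed`. If `focusMask` is given, the field decays
#' to zero outside the mask's dilation. If the masked MSE rises for three
#' consecutive iterations the best field so far is kept and a
#' converged-early warning is raised.
#'
#' @param fixed,moving [ScalarVolume-class] objects, coarsely aligned
#' @param focusMask optional [ROIMask-class]; the field is zeroed outside
#'   its `focusDilationMm` dilation
#' @param levels number of resolution levels
#' @param iterations demons iterations per level
#' @param sigmaVox Gaussian regularisation sigma in voxels
#' @param focusDilationMm dilation margin applied to `focusMask`
#' @return a [DeformationField-class] on the fixed grid
#' @export
registerDeformable <- function(fixed, moving, focusMask = NULL, levels = 3L,
                               iterations = 50L, sigmaVox = 2,
                               focusDilationMm = 10) {
    stopifnot(levels >= 1L)
    factors <- 2^((levels:1) - 1)
    u <- NULL
    earlyStop <- FALSE
    for (f in factors) {
        g <- downsampleGrid(fixed@grid, f)
        fv <- resampleToGrid(fixed, g)
        mv <- resampleToGrid(moving, g)
        if (is.null(u)) {
            ux <- uy <- uz <- numeric(prod(g@dims))
        } else {
            ux <- as.numeric(resampleToGrid(u$x, g, fill = 0)@values)
            uy <- as.numeric(resampleToGrid(u$y, g, fill = 0)@values)
            uz <- as.numeric(resampleToGrid(u$z, g, fill = 0)@values)
        }
        res <- cpp_demons(as.numeric(fv@values), as.numeric(mv@values),
                          g@dims, g@spacing, ux, uy, uz,
                          as.integer(iterations), sigmaVox,
                          defaultFill(moving@quantity))
        if (length(res$mse) < iterations) earlyStop <- TRUE
        u <- list(x = ScalarVolume(array(res$ux, g@dims), g, "label"),
                  y = ScalarVolume(array(res$uy, g@dims), g, "label"),
                  z = ScalarVolume(array(res$uz, g@dims), g, "label"))
    }
    g <- fixed@grid
    disp <- array(0, c(g@dims, 3))
    disp[, , , 1] <- u$x@values
    disp[, , , 2] <- u$y@values
    disp[, , , 3] <- u$z@values
    if (!is.null(focusMask)) {
        dil <- dilateMask(focusMask, focusDilationMm)
        w <- gaussianSmooth(ScalarVolume(array(as.numeric(dil@membership),
                                               g@dims), g, "label"),
                            sigmaMm = focusDilationMm / 2)@values
        w[!dil@membership] <- 0
        w <- pmin(1, pmax(0, w))
        for (a in 1:3) disp[, , , a] <- disp[, , , a] * w
    }
    if (earlyStop)
        warning("demons registration converged early (MSE rose for three ",
                "consecutive iterations); returning the best field")
    DeformationField(disp, g)
}
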