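#' Voxel-center world coordinates along one axis
#'
#' @param grid an [ImageGrid-class]
#' @param axis 1, 2 or 3
#' @return numeric vector of world mm positions
#' @export
voxelCoords <- function(grid, axis) {
    grid@origin[axis] + (seq_len(grid@dims[axis]) - 1) * grid@spacing[axis]
}

#' Volume of one voxel in cm^3
#'
#' @param grid an [ImageGrid-class]
#' @return scalar, cm^3
#' @export
voxelVolumeCc <- function(grid) prod(grid@spacing) / 1000

# world extent of a grid: voxel centers span [origin, origin + (n-1) sp]
gridExtent <- function(grid) {
    lo <- grid@origin
    hi <- grid@origin + (grid@dims - 1) * grid@spacing
    rbind(lo = lo, hi = hi)
}

sameGrid <- function(a, b, tol = 1e-6) {
    ga <- geometry(a); gb <- geometry(b)
    identical(ga@dims, gb@dims) &&
        all(abs(ga@spacing - gb@spacing) < tol) &&
        all(abs(ga@origin - gb@origin) < tol)
}

stopUnlessSameGrid <- function(a, b, what = "inputs") {
    if (!sameGrid(a, b))
        stop(what, " are on different grids; resample to a common grid first ",
             "(see resampleToGrid)")
    invisible(TRUE)
}

defaultFill <- function(quantity) {
    switch(quantity, HU = -1000, density = 0, dose = 0, gamma = 0, 0)
}

#' Resample a scalar volume onto a target grid
#'
#' Trilinear or nearest-neighbour pull-back interpolation; target voxels
#' outside the source extent receive `fill` (by default -1000 for HU volumes
#' and 0 for density/dose).
#'
#' @param volume a [ScalarVolume-class]
#' @param target an [ImageGrid-class]
#' @param method `"trilinear"` or `"nearest"`
#' @param fill value for voxels outside the source extent
#' @return a [ScalarVolume-class] on `target`
#' @examples
#' v <- ScalarVolume(array(100, c(8, 8, 8)))
#' g <- ImageGrid(c(4, 4, 4), spacing = 2, origin = c(0.5, 0.5, 0.5))
#' resampleToGrid(v, g)
#' @export
resampleToGrid <- function(volume, target, method = c("trilinear", "nearest"),
                           fill = NULL) {
    method <- match.arg(method)
    if (is.null(fill)) fill <- defaultFill(volume@quantity)
    src <- volume@grid
    es <- gridExtent(src); et <- gridExtent(target)
    if (any(es["hi", ] < et["lo", ]) || any(et["hi", ] < es["lo", ]))
        stop("source and target grids do not overlap in world space")
    out <- cpp_resample(as.numeric(volume@values), src@dims, src@spacing,
                        src@origin, target@dims, target@spacing,
                        target@origin, as.integer(method == "nearest"), fill)
    ScalarVolume(array(out, target@dims), target, volume@quantity)
}

#' Erode a mask by a world-space margin
#'
#' Euclidean erosion on the anisotropic world-distance transform: a voxel is
#' kept iff its distance to the mask complement exceeds `marginMm`. A margin
#' of 0 returns the input unchanged.
#'
#' @param mask an [ROIMask-class]
#' @param marginMm erosion margin, mm, >= 0
#' @param inPlaneOnly if TRUE, erode only within axial planes (the
#'   cranio-caudal direction is left untouched)
#' @return an eroded [ROIMask-class]
#' @export
erodeMask <- function(mask, marginMm, inPlaneOnly = FALSE) {
    if (!is.finite(marginMm) || marginMm < 0)
        stop("marginMm must be >= 0")
    if (marginMm == 0) return(mask)
    g <- mask@grid
    sp <- g@spacing
    if (inPlaneOnly) sp[3] <- Inf
    d2 <- cpp_edt_sq(as.logical(!mask@membership), g@dims, sp)
    keep <- mask@membership & array(d2 > marginMm^2, g@dims)
    ROIMask(keep, g, mask@name)
}

#' Dilate a mask by a world-space margin
#'
#' @param mask an [ROIMask-class]
#' @param marginMm dilation margin, mm, >= 0
#' @return a dilated [ROIMask-class]
#' @export
dilateMask <- function(mask, marginMm) {
    if (!is.finite(marginMm) || marginMm < 0)
        stop("marginMm must be >= 0")
    if (marginMm == 0) return(mask)
    g <- mask@grid
    d2 <- cpp_edt_sq(as.logical(mask@membership), g@dims, g@spacing)
    ROIMask(array(d2 <= marginMm^2, g@dims), g, mask@name)
}

#' Voxelwise intersection of two masks on one grid
#'
#' @param a,b [ROIMask-class] objects on the same grid
#' @param name name for the result
#' @return an [ROIMask-class]
#' @export
intersectMasks <- function(a, b, name = NULL) {
    stopUnlessSameGrid(a, b, "masks")
    if (is.null(name)) name <- paste0(a@name, "&", b@name)
    ROIMask(a@membership & b@membership, a@grid, name)
}

#' Voxelwise union of two masks on one grid
#'
#' @param a,b [ROIMask-class] objects on the same grid
#' @param name name for the result
#' @return an [ROIMask-class]
#' @export
unionMasks <- function(a, b, name = NULL) {
    stopUnlessSameGrid(a, b, "masks")
    if (is.null(name)) name <- paste0(a@name, "|", b@name)
    ROIMask(a@membership | b@membership, a@grid, name)
}

#' Gaussian low-pass filter of a scalar volume
#'
#' Separable Gaussian in world mm. When `mask` is given, normalised
#' (mask-weighted) convolution is used so that values do not bleed across
#' the mask boundary.
#'
#' @param volume a [ScalarVolume-class]
#' @param sigmaMm Gaussian sigma in mm (scalar or per-axis)
#' @param mask optional [ROIMask-class] restricting the support
#' @return a filtered [ScalarVolume-class]
#' @export
gaussianSmooth <- function(volume, sigmaMm, mask = NULL) {
    g <- volume@grid
    if (length(sigmaMm) == 1L) sigmaMm <- rep(sigmaMm, 3L)
    sv <- sigmaMm / g@spacing
    if (is.null(mask)) {
        out <- cpp_gaussian_blur(as.numeric(volume@values), g@dims, sv)
    } else {
        stopUnlessSameGrid(volume, mask)
        m <- as.numeric(mask@membership)
        num <- cpp_gaussian_blur(as.numeric(volume@values) * m, g@dims, sv)
        den <- cpp_gaussian_blur(m, g@dims, sv)
        out <- ifelse(den > 1e-9, num / den, 0)
        out[!mask@membership] <- 0
    }
    ScalarVolume(array(out, g@dims), g, volume@quantity)
}

eulerMatrix <- function(rotDeg) {
    r <- rotDeg * pi / 180
    cx <- cos(r[1]); sx <- sin(r[1])
    cy <- cos(r[2]); sy <- sin(r[2])
    cz <- cos(r[3]); sz <- sin(r[3])
    Rx <- rbind(c(1, 0, 0), c(0, cx, -sx), c(0, sx, cx))
    Ry <- rbind(c(cy, 0, sy), c(0, 1, 0), c(-sy, 0, cy))
    Rz <- rbind(c(cz, -sz, 0), c(sz, cz, 0), c(0, 0, 1))
    Rz %*% Ry %*% Rx
}

#' Invert a rigid transform
#'
#' @param transform a [RigidTransform-class]
#' @return the inverse [RigidTransform-class] (numerically exact composition)
#' @export
invertRigid <- function(transform) {
    # pull-back mapping is affine: y = R (x - c) + c + t; the inverse
    # pull-back uses R' and translation -R' t expressed in the same form
    R <- eulerMatrix(transform@rotation)
    # solve for Euler angles of t(R)
    Ri <- t(R)
    ry <- asin(-Ri[3, 1])
    rx <- atan2(Ri[3, 2], Ri[3, 3])
    rz <- atan2(Ri[2, 1], Ri[1, 1])
    newTrans <- as.numeric(-Ri %*% transform@translation)
    RigidTransform(rotation = c(rx, ry, rz) * 180 / pi,
                   translation = newTrans, center = transform@center)
}

#' @describeIn applyTransform resample a volume through a rigid transform
#'   (pull-back onto its own grid, or `grid` if supplied)
#' @param grid optional target [ImageGrid-class]
#' @param method interpolation, `"trilinear"` or `"nearest"`
#' @param fill fill value outside the source extent
#' @export
setMethod("applyTransform", signature("ScalarVolume", "RigidTransform"),
    function(x, transform, grid = NULL, method = "trilinear", fill = NULL) {
        if (is.null(grid)) grid <- x@grid
        if (is.null(fill)) fill <- defaultFill(x@quantity)
        R <- eulerMatrix(transform@rotation)
        out <- cpp_rigid_resample(as.numeric(x@values), x@grid@dims,
                                  x@grid@spacing, x@grid@origin, grid@dims,
                                  grid@spacing, grid@origin, R,
                                  transform@center, transform@translation,
                                  as.integer(method == "nearest"), fill)
        ScalarVolume(array(out, grid@dims), grid, x@quantity)
    })

#' @export
setMethod("applyTransform", signature("ROIMask", "RigidTransform"),
    function(x, transform, grid = NULL, ...) {
        if (is.null(grid)) grid <- x@grid
        R <- eulerMatrix(transform@rotation)
        out <- cpp_rigid_resample(as.numeric(x@membership), x@grid@dims,
                                  x@grid@spacing, x@grid@origin, grid@dims,
                                  grid@spacing, grid@origin, R,
                                  transform@center, transform@translation,
                                  1L, 0)
        ROIMask(array(out > 0.5, grid@dims), grid, x@name)
    })

#' @describeIn applyTransform warp a volume by a displacement field
#'   (pull-back: output(x) = input(x + u(x)))
#' @export
setMethod("applyTransform", signature("ScalarVolume", "DeformationField"),
    function(x, transform, method = "trilinear", fill = NULL) {
        stopUnlessSameGrid(x, transform, "volume and field")
        if (is.null(fill)) fill <- defaultFill(x@quantity)
        g <- x@grid
        u <- transform@displacement
        out <- cpp_warp(as.numeric(x@values), g@dims, g@spacing, g@origin,
                        as.numeric(u[, , , 1]), as.numeric(u[, , , 2]),
                        as.numeric(u[, , , 3]),
                        as.integer(method == "nearest"), fill)
        ScalarVolume(array(out, g@dims), g, x@quantity)
    })

#' @export
setMethod("applyTransform", signature("ROIMask", "DeformationField"),
    function(x, transform, ...) {
        stopUnlessSameGrid(x, transform, "mask and field")
        g <- x@grid
        u <- transform@displacement
        out <- cpp_warp(as.numeric(x@membership), g@dims, g@spacing,
                        g@origin, as.numeric(u[, , , 1]),
                        as.numeric(u[, , , 2]), as.numeric(u[, , , 3]),
                        1L, 0)
        ROIMask(array(out > 0.5, g@dims), g, x@name)
    })

#' @export
setMethod("applyTransform", signature("StructureSet", "DeformationField"),
    function(x, transform, ...) {
        masks <- lapply(x@masks, applyTransform, transform = transform)
        StructureSet(masks, external = x@external)
    })

#' @export
setMethod("applyTransform", signature("StructureSet", "RigidTransform"),
    function(x, transform, grid = NULL, ...) {
        masks <- lapply(x@masks, applyTransform, transform = transform,
                        grid = grid)
        StructureSet(masks, external = x@external)
    })

#' Jacobian determinant of the mapping x + u(x)
#'
#' Central finite differences on the displacement field; a positive
#' determinant everywhere means the deformation does not fold.
#'
#' @param field a [DeformationField-class]
#' @return a [ScalarVolume-class] of determinant values
#' @export
jacobianDeterminant <- function(field) {
    g <- field@grid
    u <- field@displacement
    J <- array(0, c(g@dims, 3, 3))
    for (comp in 1:3) {
        for (ax in 1:3) {
            arr <- u[, , , comp]
            n <- g@dims[ax]
            idxp <- pmin(seq_len(n) + 1L, n)
            idxm <- pmax(seq_len(n) - 1L, 1L)
            denom <- (idxp - idxm) * g@spacing[ax]
            if (ax == 1) {
                d <- (arr[idxp, , , drop = FALSE] - arr[idxm, , , drop = FALSE]) /
                    array(denom, g@dims)
            } else if (ax == 2) {
                d <- (arr[, idxp, , drop = FALSE] - arr[, idxm, , drop = FALSE]) /
                    array(rep(denom, each = g@dims[1]), g@dims)
            } else {
                d <- (arr[, , idxp, drop = FALSE] - arr[, , idxm, drop = FALSE]) /
                    array(rep(denom, each = g@dims[1] * g@dims[2]), g@dims)
            }
            J[, , , comp, ax] <- d
        }
    }
    # det(I + J) per voxel
    a11 <- 1 + J[, , , 1, 1]; a12 <- J[, , , 1, 2]; a13 <- J[, , , 1, 3]
    a21 <- J[, , , 2, 1]; a22 <- 1 + J[, , , 2, 2]; a23 <- J[, , , 2, 3]
    a31 <- J[, , , 3, 1]; a32 <- J[, , , 3, 2]; a33 <- 1 + J[, , , 3, 3]
    det <- a11 * (a22 * a33 - a23 * a32) - a12 * (a21 * a33 - a23 * a31) +
        a13 * (a21 * a32 - a22 * a31)
    ScalarVolume(array(det, g@dims), g, "gamma")
}
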