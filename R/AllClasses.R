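#' Axis-aligned 3-D image grid
#'
#' Geometry shared by all volumes: voxel counts, spacing (mm) and the world
#' position (mm) of the first voxel center. A fixed right-handed patient
#' convention is used throughout: +x patient left, +y anterior, +z cranial.
#' Voxel indices address voxel centers.
#'
#' @slot dims integer(3), voxels per axis
#' @slot spacing numeric(3), mm per voxel
#' @slot origin numeric(3), world mm of voxel (1,1,1)
#' @export
setClass("ImageGrid",
    representation(dims = "integer", spacing = "numeric", origin = "numeric"),
    validity = function(object) {
        if (length(object@dims) != 3L || any(object@dims < 1L))
            return("dims must be three integers >= 1")
        if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
            any(object@spacing <= 0))
            return("spacing must be three positive finite numbers")
        if (length(object@origin) != 3L || any(!is.finite(object@origin)))
            return("origin must be three finite numbers")
        TRUE
    })

#' Construct an [ImageGrid-class]
#'
#' @param dims voxels per axis
#' @param spacing mm per voxel (recycled if scalar)
#' @param origin world mm of the first voxel center
#' @return an `ImageGrid`
#' @examples
#' ImageGrid(c(64, 64, 32), spacing = 2.5)
#' @export
ImageGrid <- function(dims, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
    if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
    new("ImageGrid", dims = as.integer(dims), spacing = as.numeric(spacing),
        origin = as.numeric(origin))
}

#' Scalar volume on an image grid
#'
#' One scalar per voxel plus a quantity tag (`"HU"`, `"density"` in g/cm^3,
#' `"dose"` in Gy, or `"gamma"`). HU volumes must be finite; density and dose
#' must be non-negative.
#'
#' @slot grid an [ImageGrid-class]
#' @slot values 3-D numeric array matching the grid dims
#' @slot quantity character tag
#' @export
setClass("ScalarVolume",
    representation(grid = "ImageGrid", values = "array",
                   quantity = "character"),
    validity = function(object) {
        if (!identical(dim(object@values), object@grid@dims))
            return("values array dims must match grid dims")
        if (!object@quantity %in% c("HU", "density", "dose", "gamma", "label"))
            return("quantity must be one of HU, density, dose, gamma, label")
        v <- object@values
        if (object@quantity == "HU" && any(!is.finite(v)))
            return("HU values must be finite")
        if (object@quantity %in% c("density", "dose") &&
            any(v < 0, na.rm = TRUE))
            return(sprintf("%s values must be >= 0", object@quantity))
        TRUE
    })

#' Construct a [ScalarVolume-class]
#'
#' @param values 3-D numeric array
#' @param grid an [ImageGrid-class]; defaults to unit spacing
#' @param quantity `"HU"`, `"density"`, `"dose"` or `"gamma"`
#' @return a `ScalarVolume`
#' @export
ScalarVolume <- function(values, grid = NULL, quantity = "HU") {
    values <- as.array(values)
    storage.mode(values) <- "double"
    if (is.null(grid)) grid <- ImageGrid(dim(values))
    new("ScalarVolume", grid = grid, values = values, quantity = quantity)
}

#' Boolean region-of-interest mask on an image grid
#'
#' @slot grid an [ImageGrid-class]
#' @slot membership 3-D logical array
#' @slot name ROI name (e.g. `"BODY"`, `"whole_breast_CTV"`, `"heart"`)
#' @export
setClass("ROIMask",
    representation(grid = "ImageGrid", membership = "array",
                   name = "character"),
    validity = function(object) {
        if (!identical(dim(object@membership), object@grid@dims))
            return("membership array dims must match grid dims")
        if (!is.logical(object@membership))
            return("membership must be logical")
        if (anyNA(object@membership))
            return("membership must not contain NA")
        TRUE
    })

#' Construct an [ROIMask-class]
#'
#' @param membership 3-D logical array
#' @param grid an [ImageGrid-class]
#' @param name ROI name
#' @return an `ROIMask`
#' @export
ROIMask <- function(membership, grid = NULL, name = "ROI") {
    membership <- as.array(membership)
    storage.mode(membership) <- "logical"
    if (is.null(grid)) grid <- ImageGrid(dim(membership))
    new("ROIMask", grid = grid, membership = membership, name = name)
}

#' Named collection of ROI masks on one grid
#'
#' Exactly one mask is flagged as the External/BODY contour. Target volume
#' masks are expected to lie inside the External.
#'
#' @slot grid an [ImageGrid-class]
#' @slot masks named list of [ROIMask-class]
#' @slot external name of the External/BODY mask
#' @export
setClass("StructureSet",
    representation(grid = "ImageGrid", masks = "list", external = "character"),
    validity = function(object) {
        if (length(object@masks) == 0L) return("at least one mask required")
        if (is.null(names(object@masks)) || any(names(object@masks) == ""))
            return("masks must be named")
        for (m in object@masks) {
            if (!is(m, "ROIMask")) return("masks must be ROIMask objects")
            if (!identical(m@grid@dims, object@grid@dims) ||
                !isTRUE(all.equal(m@grid@spacing, object@grid@spacing)) ||
                !isTRUE(all.equal(m@grid@origin, object@grid@origin)))
                return("all masks must share the structure-set grid")
        }
        if (!object@external %in% names(object@masks))
            return("external must name one of the masks")
        TRUE
    })

#' Construct a [StructureSet-class]
#'
#' @param masks named list of [ROIMask-class] on one grid
#' @param external name of the External/BODY mask
#' @return a `StructureSet`
#' @export
StructureSet <- function(masks, external = "BODY") {
    grid <- masks[[1L]]@grid
    new("StructureSet", grid = grid, masks = masks, external = external)
}

#' Rigid transform (rotations in degrees, translation in mm)
#'
#' Pull-back convention: resampling a moving image with this transform
#' samples it at `R (x - center) + center + translation`.
#'
#' @slot rotation numeric(3) Euler angles in degrees (applied x, then y, then z)
#' @slot translation numeric(3) mm
#' @slot center numeric(3) world mm rotation center
#' @export
setClass("RigidTransform",
    representation(rotation = "numeric", translation = "numeric",
                   center = "numeric"),
    validity = function(object) {
        if (length(object@rotation) != 3L || length(object@translation) != 3L ||
            length(object@center) != 3L)
            return("rotation, translation and center must have length 3")
        if (any(!is.finite(c(object@rotation, object@translation,
                             object@center))))
            return("transform parameters must be finite")
        TRUE
    })

#' Construct a [RigidTransform-class]
#'
#' @param rotation Euler angles (degrees)
#' @param translation mm
#' @param center rotation center, world mm
#' @return a `RigidTransform`
#' @export
RigidTransform <- function(rotation = c(0, 0, 0), translation = c(0, 0, 0),
                           center = c(0, 0, 0)) {
    new("RigidTransform", rotation = as.numeric(rotation),
        translation = as.numeric(translation), center = as.numeric(center))
}

#' Dense displacement field (mm) on an image grid
#'
#' Pull-back convention: warping a volume samples it at `x + u(x)` where
#' `u` is the stored displacement. The identity deformation is all-zero.
#'
#' @slot grid an [ImageGrid-class]
#' @slot displacement 4-D numeric array `dims x 3` (mm)
#' @export
setClass("DeformationField",
    representation(grid = "ImageGrid", displacement = "array"),
    validity = function(object) {
        d <- dim(object@displacement)
        if (length(d) != 4L || !identical(d[1:3], object@grid@dims) ||
            d[4L] != 3L)
            return("displacement must be a dims x 3 array")
        if (any(!is.finite(object@displacement)))
            return("displacement components must be finite")
        TRUE
    })

#' Construct a [DeformationField-class]
#'
#' @param displacement 4-D array `dims x 3` of mm displacements
#' @param grid an [ImageGrid-class]
#' @return a `DeformationField`
#' @export
DeformationField <- function(displacement, grid = NULL) {
    if (is.null(grid)) grid <- ImageGrid(dim(displacement)[1:3])
    new("DeformationField", grid = grid,
        displacement = as.array(displacement))
}

#' Monotone piecewise-linear grey-level conversion function
#'
#' Maps CBCT grey levels to CT HU by linear interpolation between anchors,
#' with clamped extrapolation outside the anchor range.
#'
#' @slot x anchor grey levels, strictly increasing
#' @slot y anchor HU values, non-decreasing
#' @export
setClass("ConversionFunction",
    representation(x = "numeric", y = "numeric"),
    validity = function(object) {
        if (length(object@x) < 2L) return("at least 2 anchors required")
        if (length(object@x) != length(object@y))
            return("x and y must have equal length")
        if (any(diff(object@x) <= 0))
            return("anchor grey levels must be strictly increasing")
        if (any(diff(object@y) < -1e-9))
            return("anchor HU values must be non-decreasing")
        TRUE
    })

#' Ordered tissue density classes for the HU-override correction
#'
#' Default classes and mass densities: air 0.00121, lung 0.26, adipose 0.95,
#' tissue 1.05, cartilage/bone 1.6 and other 3 g/cm^3.
#'
#' @slot className character vector of class names
#' @slot density strictly increasing densities (g/cm^3)
#' @export
setClass("DensityClassTable",
    representation(className = "character", density = "numeric"),
    validity = function(object) {
        if (length(object@className) != length(object@density))
            return("one density per class required")
        if (length(object@density) < 2L) return("at least 2 classes required")
        if (any(diff(object@density) <= 0))
            return("densities must be strictly increasing with class order")
        if (any(object@density < 0)) return("densities must be >= 0")
        TRUE
    })

#' Construct the default [DensityClassTable-class]
#'
#' @param className class names
#' @param density mass densities in g/cm^3, strictly increasing
#' @return a `DensityClassTable`
#' @export
densityClassTable <- function(
        className = c("air", "lung", "adipose", "tissue", "cartilage_bone",
                      "other"),
        density = c(0.00121, 0.26, 0.95, 1.05, 1.6, 3)) {
    new("DensityClassTable", className = className, density = density)
}

#' A corrected CBCT image set
#'
#' Method tags: `"CBCT_HU"` (density override: class labels + density table,
#' raw grey levels retained unaltered), `"CBCT_CC"` (analytical conversion
#' and shading correction: HU volume) and `"CT_V"` (virtual CT: HU volume).
#'
#' @slot method one of `"CBCT_HU"`, `"CBCT_CC"`, `"CT_V"`
#' @slot hu corrected HU [ScalarVolume-class] (`CBCT_CC`, `CT_V`) or NULL
#' @slot classes integer class-label [ScalarVolume-class] (`CBCT_HU`) or NULL
#' @slot classTable the [DensityClassTable-class] (`CBCT_HU`) or NULL
#' @slot raw the unaltered input CBCT grey levels
#' @slot provenance list of inputs and parameters
#' @export
setClass("CorrectedImage",
    representation(method = "character", hu = "ANY", classes = "ANY",
                   classTable = "ANY", raw = "ANY", provenance = "list"),
    validity = function(object) {
        if (!object@method %in% c("CBCT_HU", "CBCT_CC", "CT_V"))
            return("method must be CBCT_HU, CBCT_CC or CT_V")
        if (object@method == "CBCT_HU") {
            if (is.null(object@classes) || is.null(object@classTable))
                return("CBCT_HU requires classes and classTable")
        } else if (is.null(object@hu)) {
            return(sprintf("%s requires an hu volume", object@method))
        }
        TRUE
    })

#' Gamma analysis criteria
#'
#' Global normalisation: the dose criterion is a percentage of `normDose`
#' (not of local dose). Reference voxels with dose greater than `epsilon`
#' (default exactly 0) are included.
#'
#' @slot dosePct dose criterion, % of `normDose`
#' @slot distMm distance-to-agreement criterion, mm
#' @slot normDose global normalisation dose, Gy
#' @slot refine evaluated-grid sub-voxel refinement factor (>= 1)
#' @slot capFactor search radius cap as a multiple of `distMm` (may be Inf)
#' @slot epsilon inclusion threshold on reference dose
#' @export
setClass("GammaCriteria",
    representation(dosePct = "numeric", distMm = "numeric",
                   normDose = "numeric", refine = "integer",
                   capFactor = "numeric", epsilon = "numeric"),
    validity = function(object) {
        if (object@dosePct <= 0 || object@distMm <= 0)
            return("criteria must be > 0")
        if (!is.finite(object@normDose) || object@normDose <= 0)
            return("normalisation dose must be a positive number")
        if (object@refine < 1L) return("refine must be >= 1")
        if (object@capFactor <= 0) return("capFactor must be > 0")
        TRUE
    })

#' Construct [GammaCriteria-class]
#'
#' @param dosePct dose criterion (% of the normalisation dose)
#' @param distMm distance criterion (mm)
#' @param normDose global normalisation dose (Gy)
#' @param refine sub-voxel refinement factor
#' @param capFactor search radius cap, multiples of `distMm`
#' @param epsilon reference-dose inclusion threshold
#' @return a `GammaCriteria`
#' @export
gammaCriteria <- function(dosePct, distMm, normDose, refine = 3L,
                          capFactor = 3, epsilon = 0) {
    new("GammaCriteria", dosePct = dosePct, distMm = distMm,
        normDose = normDose, refine = as.integer(refine),
        capFactor = capFactor, epsilon = epsilon)
}

#' Result of a gamma analysis
#'
#' @slot gamma gamma map as a [ScalarVolume-class] (NA outside included voxels)
#' @slot rate passing rate, % of included voxels with gamma <= 1
#' @slot nIncluded included reference voxels
#' @slot nPassed voxels with gamma <= 1
#' @slot criteria the [GammaCriteria-class] used
#' @export
setClass("GammaResult",
    representation(gamma = "ScalarVolume", rate = "numeric",
                   nIncluded = "numeric", nPassed = "numeric",
                   criteria = "GammaCriteria"),
    validity = function(object) {
        if (!is.na(object@rate) && (object@rate < 0 || object@rate > 100))
            return("passing rate must be within [0, 100]")
        g <- object@gamma@values
        if (any(g < 0, na.rm = TRUE)) return("gamma must be >= 0")
        TRUE
    })

#' Acute coronary event risk model on mean heart dose
#'
#' Two monotone linear risk curves, `baseline * (1 + slopePerGy * MHD)`, for
#' the minimum-risk (> 70 years) and maximum-risk (< 40 years) age brackets;
#' a patient's risk is a convex interpolation between them. The shipped
#' baselines are illustrative configuration values, not published estimates.
#'
#' @slot baselineMin baseline risk (%) of the minimum-risk bracket
#' @slot baselineMax baseline risk (%) of the maximum-risk bracket
#' @slot slopePerGy relative risk increase per Gy of mean heart dose
#' @export
setClass("ACEModel",
    representation(baselineMin = "numeric", baselineMax = "numeric",
                   slopePerGy = "numeric"),
    validity = function(object) {
        if (object@baselineMin < 0 || object@baselineMax < 0)
            return("baselines must be >= 0")
        if (object@baselineMin > object@baselineMax)
            return("minimum-risk baseline must not exceed maximum-risk baseline")
        if (object@slopePerGy < 0) return("slope must be >= 0")
        TRUE
    })

#' Construct an [ACEModel-class]
#'
#' @param baselineMin baseline cumulative ACE risk (%) for the > 70 y bracket
#' @param baselineMax baseline cumulative ACE risk (%) for the < 40 y bracket
#' @param slopePerGy relative excess risk per Gy mean heart dose
#' @return an `ACEModel`
#' @export
aceModel <- function(baselineMin = 1, baselineMax = 10, slopePerGy = 0.074) {
    new("ACEModel", baselineMin = baselineMin, baselineMax = baselineMax,
        slopePerGy = slopePerGy)
}
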