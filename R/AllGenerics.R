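#' @export
setGeneric("values", function(x) standardGeneric("values"))

#' @export
setGeneric("geometry", function(x) standardGeneric("geometry"))

#' @export
setGeneric("spacing", function(x) standardGeneric("spacing"))

#' @export
setGeneric("origin", function(x) standardGeneric("origin"))

#' @export
setGeneric("gridDim", function(x) standardGeneric("gridDim"))

#' @export
setGeneric("quantity", function(x) standardGeneric("quantity"))

#' @export
setGeneric("membership", function(x) standardGeneric("membership"))

#' @export
setGeneric("roiName", function(x) standardGeneric("roiName"))

#' @export
setGeneric("voxelCount", function(x) standardGeneric("voxelCount"))

#' @export
setGeneric("roiNames", function(x) standardGeneric("roiNames"))

#' @export
setGeneric("externalName", function(x) standardGeneric("externalName"))

#' @export
setGeneric("getMask", function(x, name) standardGeneric("getMask"))

#' @export
setGeneric("displacement", function(x) standardGeneric("displacement"))

#' Apply a deformation field or rigid transform by pull-back interpolation
#'
#' @param x a [ScalarVolume-class], [ROIMask-class] or [StructureSet-class]
#' @param transform a [DeformationField-class] or [RigidTransform-class]
#' @param ... further arguments (`method`, `fill`)
#' @return an object of the same class as `x`
#' @export
setGeneric("applyTransform", function(x, transform, ...)
    standardGeneric("applyTransform"))

#' @export
setGeneric("passingRate", function(x) standardGeneric("passingRate"))

#' @export
setGeneric("correctionMethod", function(x) standardGeneric("correctionMethod"))

#' @export
setGeneric("huVolume", function(x) standardGeneric("huVolume"))

#' @export
setGeneric("densityVolume", function(x, ...) standardGeneric("densityVolume"))
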