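#' @describeIn ScalarVolume voxel values as a 3-D array
#' @param x object
#' @export
setMethod("values", "ScalarVolume", function(x) x@values)

#' @export
setMethod("geometry", "ScalarVolume", function(x) x@grid)
#' @export
setMethod("geometry", "ROIMask", function(x) x@grid)
#' @export
setMethod("geometry", "StructureSet", function(x) x@grid)
#' @export
setMethod("geometry", "DeformationField", function(x) x@grid)
#' @export
setMethod("geometry", "ImageGrid", function(x) x)

#' @export
setMethod("spacing", "ImageGrid", function(x) x@spacing)
#' @export
setMethod("spacing", "ScalarVolume", function(x) x@grid@spacing)
#' @export
setMethod("spacing", "ROIMask", function(x) x@grid@spacing)

#' @export
setMethod("origin", "ImageGrid", function(x) x@origin)
#' @export
setMethod("origin", "ScalarVolume", function(x) x@grid@origin)

#' @export
setMethod("gridDim", "ImageGrid", function(x) x@dims)
#' @export
setMethod("gridDim", "ScalarVolume", function(x) x@grid@dims)
#' @export
setMethod("gridDim", "ROIMask", function(x) x@grid@dims)

#' @export
setMethod("quantity", "ScalarVolume", function(x) x@quantity)

#' @export
setMethod("membership", "ROIMask", function(x) x@membership)

#' @export
setMethod("roiName", "ROIMask", function(x) x@name)

#' @describeIn ROIMask number of TRUE voxels
#' @param x object
#' @export
setMethod("voxelCount", "ROIMask", function(x) sum(x@membership))

#' @export
setMethod("roiNames", "StructureSet", function(x) names(x@masks))

#' @export
setMethod("externalName", "StructureSet", function(x) x@external)

#' @describeIn StructureSet extract one mask by name
#' @param x object
#' @param name ROI name
#' @export
setMethod("getMask", "StructureSet", function(x, name) {
    if (!name %in% names(x@masks))
        stop("no ROI named '", name, "' in structure set")
    x@masks[[name]]
})

#' @export
setMethod("displacement", "DeformationField", function(x) x@displacement)

#' @export
setMethod("passingRate", "GammaResult", function(x) x@rate)

#' @export
setMethod("correctionMethod", "CorrectedImage", function(x) x@method)

#' @describeIn CorrectedImage the HU volume used for HU accuracy metrics:
#'   the corrected HU for `CBCT_CC`/`CT_V`, the unaltered raw grey levels
#'   for `CBCT_HU`
#' @param x object
#' @export
setMethod("huVolume", "CorrectedImage", function(x) {
    if (x@method == "CBCT_HU") x@raw else x@hu
})

setMethod("show", "ImageGrid", function(object) {
    cat(sprintf("ImageGrid %d x %d x %d voxels, spacing (%g, %g, %g) mm\n",
                object@dims[1], object@dims[2], object@dims[3],
                object@spacing[1], object@spacing[2], object@spacing[3]))
    cat(sprintf("  origin (%g, %g, %g) mm\n", object@origin[1],
                object@origin[2], object@origin[3]))
})

setMethod("show", "ScalarVolume", function(object) {
    r <- range(object@values, na.rm = TRUE)
    cat(sprintf("ScalarVolume [%s] %d x %d x %d, range [%.4g, %.4g]\n",
                object@quantity, object@grid@dims[1], object@grid@dims[2],
                object@grid@dims[3], r[1], r[2]))
})

setMethod("show", "ROIMask", function(object) {
    cat(sprintf("ROIMask '%s': %d of %d voxels\n", object@name,
                sum(object@membership), prod(object@grid@dims)))
})

setMethod("show", "StructureSet", function(object) {
    cat(sprintf("StructureSet with %d ROIs (External: %s)\n",
                length(object@masks), object@external))
    for (nm in names(object@masks))
        cat(sprintf("  %-20s %d voxels\n", nm,
                    sum(object@masks[[nm]]@membership)))
})

setMethod("show", "RigidTransform", function(object) {
    cat(sprintf("RigidTransform rot (%.3g, %.3g, %.3g) deg, trans (%.3g, %.3g, %.3g) mm\n",
                object@rotation[1], object@rotation[2], object@rotation[3],
                object@translation[1], object@translation[2],
                object@translation[3]))
})

setMethod("show", "DeformationField", function(object) {
    mag <- sqrt(object@displacement[, , , 1]^2 +
                object@displacement[, , , 2]^2 +
                object@displacement[, , , 3]^2)
    cat(sprintf("DeformationField %d x %d x %d, |u| max %.3g mm\n",
                object@grid@dims[1], object@grid@dims[2],
                object@grid@dims[3], max(mag)))
})

setMethod("show", "CorrectedImage", function(object) {
    cat(sprintf("CorrectedImage method %s\n", object@method))
})

setMethod("show", "GammaResult", function(object) {
    cat(sprintf("GammaResult %g%%/%g mm: %.2f%% passing (%d of %d voxels)\n",
                object@criteria@dosePct, object@criteria@distMm, object@rate,
                as.integer(object@nPassed), as.integer(object@nIncluded)))
})
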