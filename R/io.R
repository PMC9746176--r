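#' Read a scalar volume from NIfTI or NRRD
#'
#' The format is inferred from the file extension (`.nii`, `.nii.gz`,
#' `.nrrd`) unless given. Images are expected in the package's axis-aligned
#' patient convention; spacing is taken from the stored transform and the
#' origin from its translation.
#'
#' @param path file path
#' @param format `"nifti"`, `"nrrd"` or `"auto"`
#' @param quantity quantity tag for the result
#' @return a [ScalarVolume-class]
#' @export
readVolume <- function(path, format = c("auto", "nifti", "nrrd"),
                       quantity = "HU") {
    format <- match.arg(format)
    if (!file.exists(path)) stop("cannot read volume: no such file: ", path)
    if (format == "auto") format <- guessFormat(path)
    if (format == "nifti") readNiftiVolume(path, quantity)
    else readNrrdVolume(path, quantity)
}

#' Write a scalar volume to NIfTI or NRRD
#'
#' Values are stored as 64-bit floats so that write/read round-trips are
#' bit-exact.
#'
#' @param volume a [ScalarVolume-class]
#' @param path output path (`.nii`, `.nii.gz` or `.nrrd`)
#' @param format `"nifti"`, `"nrrd"` or `"auto"`
#' @return `path`, invisibly
#' @export
writeVolume <- function(volume, path, format = c("auto", "nifti", "nrrd")) {
    format <- match.arg(format)
    if (format == "auto") format <- guessFormat(path)
    if (format == "nifti") writeNiftiVolume(volume, path)
    else writeNrrdVolume(volume, path)
    invisible(path)
}

guessFormat <- function(path) {
    if (grepl("\\.nrrd$", path, ignore.case = TRUE)) "nrrd"
    else if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) "nifti"
    else stop("cannot infer volume format from extension of: ", path)
}

readNiftiVolume <- function(path, quantity) {
    img <- tryCatch(RNifti::readNifti(path, internal = FALSE),
                    error = function(e)
                        stop("failed to read NIfTI file ", path, ": ",
                             conditionMessage(e)))
    arr <- as.array(img)
    arr <- array(as.numeric(arr), dim(arr)) # drop image-class attributes
    if (length(dim(arr)) == 2L) dim(arr) <- c(dim(arr), 1L)
    if (length(dim(arr)) != 3L)
        stop("NIfTI file ", path, " is not a 3-D volume")
    xf <- RNifti::xform(img)
    sp <- sqrt(colSums(xf[1:3, 1:3]^2))
    rot <- sweep(xf[1:3, 1:3], 2, sp, "/")
    if (max(abs(rot - diag(3))) > 1e-3)
        stop("NIfTI file ", path, " has a non-identity orientation; ",
             "reorient it to the package's axis-aligned patient convention")
    grid <- ImageGrid(dim(arr), spacing = sp, origin = xf[1:3, 4])
    ScalarVolume(arr, grid, quantity)
}

writeNiftiVolume <- function(volume, path) {
    niftiFromArray(volume@values, volume@grid, "double", path)
}

niftiFromArray <- function(arr, grid, datatype, path) {
    attr(arr, "pixdim") <- grid@spacing
    attr(arr, "pixunits") <- c("mm", "s")
    img <- RNifti::asNifti(arr, datatype = datatype)
    xf <- diag(4)
    diag(xf)[1:3] <- grid@spacing
    xf[1:3, 4] <- grid@origin
    RNifti::qform(img) <- structure(xf, code = 2L)
    RNifti::writeNifti(img, path)
}

# --- minimal NRRD support (3-D, double/float/short, raw or gzip) ---------

readNrrdVolume <- function(path, quantity) {
    bytes <- readBin(path, "raw", n = file.size(path))
    # header and data are separated by a blank line
    nl <- which(bytes == as.raw(10L))
    split <- NA_integer_
    for (i in seq_along(nl)[-1]) {
        if (nl[i] == nl[i - 1] + 1L ||
            (nl[i] == nl[i - 1] + 2L && bytes[nl[i] - 1L] == as.raw(13L))) {
            split <- nl[i]
            break
        }
    }
    if (is.na(split)) stop("truncated NRRD header in ", path)
    header <- strsplit(rawToChar(bytes[seq_len(split)]), "\r?\n")[[1]]
    if (length(header) == 0L || !grepl("^NRRD", header[1]))
        stop("not an NRRD file (bad magic): ", path)
    fields <- list()
    for (line in header[-1]) {
        if (line == "" || grepl("^#", line)) next
        kv <- regmatches(line, regexec("^([^:]+):=?\\s*(.*)$", line))[[1]]
        if (length(kv) == 3L) fields[[tolower(trimws(kv[2]))]] <- trimws(kv[3])
    }
    need <- function(key) {
        if (is.null(fields[[key]]))
            stop("NRRD header of ", path, " lacks required field '", key, "'")
        fields[[key]]
    }
    if (as.integer(need("dimension")) != 3L)
        stop("only 3-D NRRD volumes are supported: ", path)
    sizes <- as.integer(strsplit(need("sizes"), "\\s+")[[1]])
    type <- need("type")
    enc <- tolower(need("encoding"))
    sp <- c(1, 1, 1)
    if (!is.null(fields[["spacings"]])) {
        sp <- as.numeric(strsplit(fields[["spacings"]], "\\s+")[[1]])
    } else if (!is.null(fields[["space directions"]])) {
        dirs <- gsub("[()]", "", strsplit(fields[["space directions"]],
                                          "\\)\\s*\\(")[[1]])
        m <- vapply(strsplit(dirs, ","),
                    function(x) as.numeric(x), numeric(3))
        sp <- sqrt(colSums(m^2))
    }
    org <- c(0, 0, 0)
    if (!is.null(fields[["space origin"]]))
        org <- as.numeric(strsplit(gsub("[()]", "",
                                        fields[["space origin"]]), ",")[[1]])
    n <- prod(sizes)
    what <- switch(type,
        double = "double", float = "double", short = "integer",
        int = "integer", `unsigned char` = "integer", uchar = "integer",
        stop("unsupported NRRD type '", type, "' in ", path))
    size <- switch(type, double = 8L, float = 4L, short = 2L, int = 4L,
                   `unsigned char` = 1L, uchar = 1L)
    signed <- !type %in% c("unsigned char", "uchar")
    payload <- bytes[(split + 1L):length(bytes)]
    if (enc == "gzip") payload <- memDecompress(payload, type = "gzip")
    else if (enc != "raw")
        stop("unsupported NRRD encoding '", enc, "' in ", path)
    vals <- readBin(payload, what = what, n = n, size = size, signed = signed,
                    endian = "little")
    if (length(vals) < n)
        stop("truncated NRRD data in ", path, ": expected ", n, " values, got ",
             length(vals))
    grid <- ImageGrid(sizes, spacing = sp, origin = org)
    ScalarVolume(array(as.numeric(vals), sizes), grid, quantity)
}

writeNrrdVolume <- function(volume, path, gzip = FALSE) {
    g <- volume@grid
    hdr <- c("NRRD0004",
             "# written by cbctdose",
             "type: double",
             "dimension: 3",
             "space: right-anterior-superior",
             sprintf("sizes: %d %d %d", g@dims[1], g@dims[2], g@dims[3]),
             sprintf("space directions: (%.17g,0,0) (0,%.17g,0) (0,0,%.17g)",
                     g@spacing[1], g@spacing[2], g@spacing[3]),
             "kinds: domain domain domain",
             "endian: little",
             sprintf("encoding: %s", if (gzip) "gzip" else "raw"),
             sprintf("space origin: (%.17g,%.17g,%.17g)",
                     g@origin[1], g@origin[2], g@origin[3]))
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(charToRaw(paste0(paste(hdr, collapse = "\n"), "\n\n")), con)
    payload <- writeBin(as.numeric(volume@values), raw(), size = 8L,
                        endian = "little")
    if (gzip) payload <- memCompress(payload, type = "gzip")
    writeBin(payload, con)
    invisible(path)
}

#' Write a structure set to a directory
#'
#' Masks are stored as 0/1 uint8 NIfTI label volumes plus a JSON manifest
#' naming each ROI and flagging the External.
#'
#' @param structures a [StructureSet-class]
#' @param dir output directory (created if missing)
#' @return `dir`, invisibly
#' @export
writeStructureSet <- function(structures, dir) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    manifest <- list(external = structures@external, rois = list())
    for (nm in names(structures@masks)) {
        fn <- paste0(gsub("[^A-Za-z0-9_.-]", "_", nm), ".nii.gz")
        m <- structures@masks[[nm]]
        niftiFromArray(array(as.integer(m@membership), m@grid@dims),
                       m@grid, "uint8", file.path(dir, fn))
        manifest$rois[[length(manifest$rois) + 1L]] <-
            list(name = nm, file = fn)
    }
    jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    invisible(dir)
}

#' Read a structure set written by [writeStructureSet()]
#'
#' @param dir directory containing `manifest.json` and mask volumes
#' @return a [StructureSet-class]
#' @export
readStructureSet <- function(dir) {
    mf <- file.path(dir, "manifest.json")
    if (!file.exists(mf)) stop("no manifest.json in ", dir)
    manifest <- jsonlite::read_json(mf)
    masks <- list()
    for (roi in manifest$rois) {
        vol <- readNiftiVolume(file.path(dir, roi$file), "HU")
        masks[[roi$name]] <- ROIMask(vol@values > 0.5, vol@grid, roi$name)
    }
    StructureSet(masks, external = manifest$external)
}
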