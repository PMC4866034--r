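#' Read a 3-D volume from NIfTI or NRRD
#'
#' Reads `.nii`, `.nii.gz` (through the RNifti package) or `.nrrd`
#' (raw-encoding NRRD, parsed natively). Voxel spacing is taken from the file
#' header. Intensities must be non-negative integers: files containing
#' fractional or negative values are rejected with an error rather than
#' quantized, so the affinity lookup table stays exact.
#'
#' @param path Path to a `.nii`, `.nii.gz` or `.nrrd` file.
#' @param intensity_max Largest representable intensity for the returned
#'   volume; defaults to 4095 (12-bit) or the data maximum if larger.
#' @return A [volume3d()].
#' @seealso [write_volume()], [read_scene()]
#' @export
read_volume <- function(path, intensity_max = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- read_any_volume(path)
  v <- raw$data
  if (anyNA(v)) stop("volume contains NA voxels")
  if (any(v < 0)) stop("negative intensities; input must be pre-quantized and non-negative")
  if (is.double(v) && any(v != round(v)))
    stop("non-integer intensities; input must be pre-quantized")
  if (is.null(intensity_max)) intensity_max <- max(4095L, max(v))
  volume3d(v, spacing = raw$spacing, intensity_max = intensity_max)
}

#' Read a fuzzy scene written by [write_volume()]
#'
#' Scenes are stored as 32-bit float volumes; this reads one back as a plain
#' numeric array (values in `[0, 1]`) with the header spacing attached as the
#' `"spacing"` attribute. Intended for comparing saved runs with
#' [error_points()].
#'
#' @param path Path to a `.nii`, `.nii.gz` or `.nrrd` file.
#' @return 3-D numeric array with a `"spacing"` attribute.
#' @export
read_scene <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- read_any_volume(path)
  out <- raw$data
  storage.mode(out) <- "double"
  attr(out, "spacing") <- raw$spacing
  out
}

#' Write a volume or fuzzy scene to NIfTI or NRRD
#'
#' The file format is chosen from the extension (`.nii`, `.nii.gz`, `.nrrd`).
#' Integer volumes are stored as 32-bit integers and round-trip bit-exactly;
#' fuzzy scenes are stored as 32-bit floats. Header spacing is preserved.
#'
#' @param vol A [volume3d()] or [fuzzy_scene()].
#' @param path Output path; the extension selects the format.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  if (dir.exists(path)) stop("`path` is a directory: ", path)
  if (inherits(vol, "volume3d")) {
    data <- vol$data; spacing <- vol$spacing; dtype <- "int32"
  } else if (inherits(vol, "fuzzy_scene")) {
    data <- vol$values; spacing <- vol$spacing; dtype <- "float"
  } else stop("`vol` must be a volume3d or fuzzy_scene")
  ext <- volume_format(path)
  if (ext == "nifti") {
    img <- RNifti::asNifti(data)
    img <- RNifti::`pixdim<-`(img, spacing)
    RNifti::writeNifti(img, path, datatype = dtype)
  } else {
    write_nrrd(data, spacing, path, dtype)
  }
  invisible(path)
}

volume_format <- function(path) {
  if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) return("nifti")
  if (grepl("\\.nrrd$", path, ignore.case = TRUE)) return("nrrd")
  stop("unsupported volume format (expect .nii, .nii.gz or .nrrd): ", path)
}

read_any_volume <- function(path) {
  if (volume_format(path) == "nifti") {
    img <- RNifti::readNifti(path)
    d <- dim(img)
    if (is.null(d)) d <- length(img)
    if (length(d) > 3L) {
      if (any(d[-(1:3)] != 1L)) stop("expected a 3-D volume, got ", length(d), " dimensions")
      d <- d[1:3]
    }
    d <- c(d, rep(1L, 3L - length(d)))  # NIfTI drops trailing singleton dims
    sp <- c(RNifti::pixdim(img), rep(1, 3))[1:3]
    list(data = array(as.vector(img), d), spacing = as.numeric(sp))
  } else {
    read_nrrd(path)
  }
}

# --- minimal NRRD (raw encoding) ----------------------------------------
# Covers the subset this package writes plus common scalar types; no R NRRD
# reader exists in the dependency set, so the format is handled natively.

nrrd_types <- list(
  uchar  = list(what = "integer", size = 1L, signed = FALSE),
  uint8  = list(what = "integer", size = 1L, signed = FALSE),
  short  = list(what = "integer", size = 2L, signed = TRUE),
  int16  = list(what = "integer", size = 2L, signed = TRUE),
  ushort = list(what = "integer", size = 2L, signed = FALSE),
  uint16 = list(what = "integer", size = 2L, signed = FALSE),
  int    = list(what = "integer", size = 4L, signed = TRUE),
  int32  = list(what = "integer", size = 4L, signed = TRUE),
  float  = list(what = "double", size = 4L, signed = TRUE),
  double = list(what = "double", size = 8L, signed = TRUE)
)

write_nrrd <- function(data, spacing, path, dtype) {
  type <- switch(dtype, int32 = "int32", float = "float",
                 stop("unsupported NRRD write type: ", dtype))
  d <- dim(data)
  hdr <- c("NRRD0004",
           paste0("type: ", type),
           "dimension: 3",
           paste0("sizes: ", paste(d, collapse = " ")),
           paste0("spacings: ", paste(format(spacing, digits = 17), collapse = " ")),
           "encoding: raw",
           "endian: little",
           "")
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw(paste0(paste(hdr, collapse = "\n"), "\n")), con)
  if (type == "int32") {
    writeBin(as.integer(data), con, size = 4L, endian = "little")
  } else {
    writeBin(as.numeric(data), con, size = 4L, endian = "little")
  }
  invisible(path)
}

read_nrrd <- function(path) {
  bytes <- readBin(path, "raw", n = file.size(path))
  # header ends at the first blank line
  nl <- which(bytes == as.raw(10L))
  hdr_end <- NA_integer_
  prev <- 0L
  for (i in nl) {
    if (i == prev + 1L) { hdr_end <- i; break }
    # tolerate \r\n
    if (i == prev + 2L && bytes[i - 1L] == as.raw(13L)) { hdr_end <- i; break }
    prev <- i
  }
  if (is.na(hdr_end)) stop("malformed NRRD: no blank line terminating the header")
  hdr <- strsplit(rawToChar(bytes[seq_len(hdr_end)]), "\r?\n")[[1]]
  if (!grepl("^NRRD000", hdr[1])) stop("not an NRRD file: ", path)
  fields <- list()
  for (line in hdr[-1]) {
    if (line == "" || grepl("^#", line)) next
    m <- regmatches(line, regexec("^([^:]+):=?\\s*(.*)$", line))[[1]]
    if (length(m) == 3L) fields[[tolower(trimws(m[2]))]] <- trimws(m[3])
  }
  type <- fields[["type"]]
  if (is.null(type) || is.null(nrrd_types[[type]]))
    stop("unsupported NRRD type: ", if (is.null(type)) "<missing>" else type)
  if (!identical(fields[["encoding"]], "raw"))
    stop("only raw-encoded NRRD is supported")
  if (!identical(as.integer(fields[["dimension"]]), 3L))
    stop("expected a 3-D NRRD volume")
  sizes <- as.integer(strsplit(fields[["sizes"]], "\\s+")[[1]])
  spacing <- if (!is.null(fields[["spacings"]]))
    as.numeric(strsplit(fields[["spacings"]], "\\s+")[[1]]) else c(1, 1, 1)
  endian <- if (!is.null(fields[["endian"]])) fields[["endian"]] else "little"
  tp <- nrrd_types[[type]]
  n <- prod(sizes)
  con <- rawConnection(bytes[(hdr_end + 1L):length(bytes)])
  on.exit(close(con))
  v <- readBin(con, tp$what, n = n, size = tp$size, signed = tp$signed,
               endian = endian)
  if (length(v) != n) stop("truncated NRRD data block")
  list(data = array(v, dim = sizes), spacing = spacing)
}
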