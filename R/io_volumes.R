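# Volume IO: NIfTI-1 (RNifti), NRRD, raw + JSON sidecar, DICOM series (read
# only).  All readers return a voxel_grid with spacing taken from file
# metadata; all downstream modules consume only the in-memory types.

guess_volume_format <- function(path) {
  if (dir.exists(path)) return("dicom")
  lp <- tolower(path)
  if (grepl("\\.nii(\\.gz)?$", lp)) return("nifti")
  if (grepl("\\.(nrrd|nhdr)$", lp)) return("nrrd")
  if (grepl("\\.raw$", lp)) return("raw")
  stop("cannot infer volume format from path: ", path, call. = FALSE)
}

#' Read a CT volume
#'
#' Supported containers: a DICOM series directory (uncompressed little-endian
#' transfer syntaxes; slices sorted by position along the slice normal, with
#' a 10% slice-spacing uniformity tolerance; rescale slope/intercept applied
#' so values are CT numbers), NIfTI-1 (`.nii`, `.nii.gz`), NRRD
#' (`.nrrd`/`.nhdr`, raw or gzip encoding) and raw (`.raw` with a JSON
#' sidecar declaring dims, spacing, origin and dtype).
#'
#' @param path File or (for DICOM) directory path.
#' @param format `"auto"` (infer from the path) or one of `"dicom"`,
#'   `"nifti"`, `"nrrd"`, `"raw"`.
#' @return A [voxel_grid()].
#' @export
read_volume <- function(path, format = c("auto", "dicom", "nifti", "nrrd", "raw")) {
  format <- match.arg(format)
  if (!file.exists(path))
    stop("cannot read volume: file not found: ", path, call. = FALSE)
  if (format == "auto") format <- guess_volume_format(path)
  switch(format,
         dicom = read_dicom_series(path),
         nifti = read_nifti_volume(path),
         nrrd = read_nrrd_volume(path),
         raw = read_raw_volume(path))
}

#' Write a volume
#'
#' Writes a [voxel_grid()] (or a binary/label volume, whose values are
#' stored as integers) so that [read_volume()] recovers dims, spacing
#' (within 1e-6 mm) and values within the quantization of the chosen dtype.
#'
#' @param grid A lattice volume.
#' @param path Output path; extension selects the container unless `format`
#'   is given.
#' @param format `"auto"`, `"nifti"`, `"nrrd"` or `"raw"` (DICOM write is
#'   not supported).
#' @param dtype Storage type: `"double"`, `"float32"`, `"int32"`, `"int16"`
#'   or `"uint8"`.  Integer dtypes round the values.
#' @return Invisibly, `path`.
#' @export
write_volume <- function(grid, path,
                         format = c("auto", "nifti", "nrrd", "raw", "dicom"),
                         dtype = "double") {
  format <- match.arg(format)
  dtype <- match.arg(dtype, c("double", "float32", "int32", "int16", "uint8"))
  vals <- grid$values
  storage.mode(vals) <- "double"
  g <- voxel_grid(vals, grid$spacing, grid$origin)
  if (format == "auto") format <- guess_volume_format(path)
  if (format == "dicom")
    stop("unsupported volume output format: dicom", call. = FALSE)
  switch(format,
         nifti = write_nifti_volume(g, path, dtype),
         nrrd = write_nrrd_volume(g, path, dtype),
         raw = write_raw_volume(g, path, dtype))
  invisible(path)
}

# ---- NIfTI (RNifti) --------------------------------------------------------

read_nifti_volume <- function(path) {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  attributes(arr) <- list(dim = dim(img))
  sp <- abs(RNifti::pixdim(img))[1:3]
  x <- RNifti::xform(img)
  origin <- if (!is.null(attr(x, "code")) && attr(x, "code") > 0) {
    as.double(x[1:3, 4])
  } else c(0, 0, 0)
  voxel_grid(arr, sp, origin)
}

nifti_dtype <- function(dtype) {
  switch(dtype, double = "double", float32 = "float", int32 = "int32",
         int16 = "int16", uint8 = "uint8")
}

write_nifti_volume <- function(g, path, dtype) {
  vals <- g$values
  if (dtype %in% c("int32", "int16", "uint8")) vals <- round(vals)
  img <- RNifti::asNifti(vals)
  aff <- structure(rbind(cbind(diag(g$spacing), g$origin), c(0, 0, 0, 1)),
                   code = 2L)
  img <- RNifti::`sform<-`(img, aff)
  img <- RNifti::`qform<-`(img, aff)
  RNifti::pixdim(img) <- g$spacing
  RNifti::writeNifti(img, path, datatype = nifti_dtype(dtype))
}

# ---- NRRD ------------------------------------------------------------------

nrrd_types <- data.frame(
  dtype = c("double", "float32", "int32", "int16", "uint8"),
  nrrd = c("double", "float", "int", "short", "uchar"),
  what = c("numeric", "numeric", "integer", "integer", "integer"),
  size = c(8L, 4L, 4L, 2L, 1L),
  signed = c(TRUE, TRUE, TRUE, TRUE, FALSE),
  stringsAsFactors = FALSE)

write_nrrd_volume <- function(g, path, dtype) {
  ti <- nrrd_types[nrrd_types$dtype == dtype, ]
  d <- dim(g$values)
  hdr <- c(
    "NRRD0004",
    "# endocast volume",
    paste0("type: ", ti$nrrd),
    "dimension: 3",
    paste0("sizes: ", paste(d, collapse = " ")),
    "encoding: raw",
    "endian: little",
    "space dimension: 3",
    sprintf("space directions: (%.17g,0,0) (0,%.17g,0) (0,0,%.17g)",
            g$spacing[1], g$spacing[2], g$spacing[3]),
    sprintf("space origin: (%.17g,%.17g,%.17g)",
            g$origin[1], g$origin[2], g$origin[3]))
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(paste0(paste(hdr, collapse = "\n"), "\n\n"), con, eos = NULL)
  vals <- as.vector(g$values)
  if (ti$what == "integer") {
    vals <- as.integer(round(vals))
    writeBin(vals, con, size = ti$size, endian = "little")
  } else {
    writeBin(vals, con, size = ti$size, endian = "little")
  }
}

parse_nrrd_triples <- function(s) {
  m <- regmatches(s, gregexpr("\\(([^)]*)\\)", s))[[1]]
  lapply(m, function(x)
    as.double(strsplit(gsub("[()]", "", x), ",")[[1]]))
}

read_nrrd_volume <- function(path) {
  bytes <- readBin(path, "raw", file.size(path))
  # header ends at the first blank line
  nl <- which(bytes == as.raw(10L))
  hdr_end <- NA_integer_
  prev <- 0L
  for (p in nl) {
    if (p == prev + 1L) { hdr_end <- p; break }
    prev <- p
  }
  if (is.na(hdr_end)) stop("malformed NRRD: no end-of-header blank line",
                           call. = FALSE)
  hdr <- strsplit(rawToChar(bytes[seq_len(hdr_end - 2L)]), "\n")[[1]]
  if (!grepl("^NRRD", hdr[1])) stop("not an NRRD file: ", path, call. = FALSE)
  fields <- list()
  for (ln in hdr[-1]) {
    if (grepl("^#", ln) || !grepl(":", ln)) next
    kv <- regmatches(ln, regexpr(":", ln), invert = TRUE)[[1]]
    fields[[trimws(tolower(kv[1]))]] <- trimws(kv[2])
  }
  dtype_nrrd <- fields[["type"]]
  ti <- nrrd_types[nrrd_types$nrrd == dtype_nrrd, ]
  if (nrow(ti) != 1L)
    stop("unsupported NRRD type: ", dtype_nrrd, call. = FALSE)
  d <- as.integer(strsplit(fields[["sizes"]], "\\s+")[[1]])
  if (length(d) != 3L) stop("only 3D NRRD supported", call. = FALSE)
  enc <- fields[["encoding"]]
  payload <- bytes[(hdr_end + 1L):length(bytes)]
  if (identical(enc, "gzip") || identical(enc, "gz")) {
    payload <- memDecompress(payload, type = "gzip")
  } else if (!identical(enc, "raw")) {
    stop("unsupported NRRD encoding: ", enc, call. = FALSE)
  }
  n <- prod(d)
  if (length(payload) != n * ti$size)
    stop("malformed NRRD: payload size ", length(payload),
         " does not match sizes field (expected ", n * ti$size, " bytes)",
         call. = FALSE)
  endian <- if (!is.null(fields[["endian"]])) fields[["endian"]] else "little"
  vals <- readBin(payload, ti$what, n = n, size = ti$size,
                  signed = ti$signed, endian = endian)
  spacing <- c(1, 1, 1)
  if (!is.null(fields[["space directions"]])) {
    tr <- parse_nrrd_triples(fields[["space directions"]])
    spacing <- vapply(seq_along(tr), function(i) sqrt(sum(tr[[i]]^2)), 0)
  } else if (!is.null(fields[["spacings"]])) {
    spacing <- as.double(strsplit(fields[["spacings"]], "\\s+")[[1]])
  }
  origin <- c(0, 0, 0)
  if (!is.null(fields[["space origin"]]))
    origin <- parse_nrrd_triples(fields[["space origin"]])[[1]]
  voxel_grid(array(as.double(vals), d), spacing, origin)
}

# ---- raw + JSON sidecar ----------------------------------------------------

raw_sidecar_path <- function(path) sub("\\.raw$", ".json", path)

write_raw_volume <- function(g, path, dtype) {
  ti <- nrrd_types[nrrd_types$dtype == dtype, ]
  con <- file(path, "wb")
  on.exit(close(con))
  vals <- as.vector(g$values)
  if (ti$what == "integer") vals <- as.integer(round(vals))
  writeBin(vals, con, size = ti$size, endian = "little")
  jsonlite::write_json(list(dims = dim(g$values), spacing = g$spacing,
                            origin = g$origin, dtype = dtype,
                            endian = "little"),
                       raw_sidecar_path(path), auto_unbox = TRUE, digits = NA)
}

read_raw_volume <- function(path) {
  sc_path <- raw_sidecar_path(path)
  if (!file.exists(sc_path))
    stop("raw volume sidecar not found: ", sc_path, call. = FALSE)
  sc <- jsonlite::read_json(sc_path, simplifyVector = TRUE)
  ti <- nrrd_types[nrrd_types$dtype == sc$dtype, ]
  if (nrow(ti) != 1L) stop("unsupported raw dtype: ", sc$dtype, call. = FALSE)
  d <- as.integer(sc$dims)
  n <- prod(d)
  if (file.size(path) != n * ti$size)
    stop("malformed raw volume: file size ", file.size(path),
         " does not match declared dims (expected ", n * ti$size, " bytes)",
         call. = FALSE)
  vals <- readBin(path, ti$what, n = n, size = ti$size, signed = ti$signed,
                  endian = sc$endian)
  voxel_grid(array(as.double(vals), d), as.double(sc$spacing),
             as.double(sc$origin))
}
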