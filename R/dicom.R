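# Minimal DICOM series reader for clinical CT: uncompressed little-endian
# transfer syntaxes (implicit and explicit VR), single-frame grayscale
# slices.  Only the handful of tags needed to assemble a volume are kept.
# Undefined-length sequences are rejected with a clear error; clinical CT
# exports of the relevant era are flat datasets.

dcm_u16 <- function(bytes, pos) {
  readBin(bytes[pos:(pos + 1L)], "integer", size = 2L, signed = FALSE,
          endian = "little")
}
dcm_u32 <- function(bytes, pos) {
  v <- readBin(bytes[pos:(pos + 3L)], "integer", size = 4L, endian = "little")
  if (v < 0) v <- v + 2^32
  v
}

# VRs that use the 12-byte (reserved + 4-byte length) explicit header form.
DCM_LONG_VRS <- c("OB", "OW", "OF", "OD", "OL", "SQ", "UC", "UR", "UT", "UN")

parse_dicom_file <- function(path) {
  bytes <- readBin(path, "raw", file.size(path))
  if (length(bytes) < 140L || rawToChar(bytes[129:132]) != "DICM")
    stop("not a DICOM part-10 file (missing DICM marker): ", path,
         call. = FALSE)
  pos <- 133L
  explicit <- TRUE       # file meta group is always explicit little-endian
  ts <- "1.2.840.10008.1.2.1"
  tags <- list()
  in_meta <- TRUE
  while (pos + 7L <= length(bytes)) {
    group <- dcm_u16(bytes, pos)
    elem <- dcm_u16(bytes, pos + 2L)
    if (in_meta && group != 0x0002L) {
      # leaving the file meta: switch to the negotiated transfer syntax
      in_meta <- FALSE
      if (ts == "1.2.840.10008.1.2") {
        explicit <- FALSE
      } else if (ts == "1.2.840.10008.1.2.1") {
        explicit <- TRUE
      } else {
        stop("unsupported DICOM transfer syntax ", ts, " in ", path,
             " (only uncompressed little-endian is supported)", call. = FALSE)
      }
    }
    use_explicit <- explicit || group == 0x0002L
    if (use_explicit) {
      vr <- rawToChar(bytes[(pos + 4L):(pos + 5L)])
      if (vr %in% DCM_LONG_VRS) {
        len <- dcm_u32(bytes, pos + 8L)
        hdr <- 12L
      } else {
        len <- dcm_u16(bytes, pos + 6L)
        hdr <- 8L
      }
    } else {
      vr <- NA_character_
      len <- dcm_u32(bytes, pos + 4L)
      hdr <- 8L
    }
    if (len == 4294967295) # 0xFFFFFFFF
      stop("undefined-length DICOM sequences are not supported (", path, ")",
           call. = FALSE)
    vstart <- pos + hdr
    if (vstart + len - 1L > length(bytes))
      stop("truncated DICOM element in ", path, call. = FALSE)
    key <- sprintf("%04X,%04X", group, elem)
    wanted <- c("0002,0010", "0020,0032", "0020,0037", "0028,0010",
                "0028,0011", "0028,0030", "0028,0100", "0028,0103",
                "0028,1052", "0028,1053", "7FE0,0010")
    if (key %in% wanted) {
      val <- bytes[vstart:(vstart + len - 1L)]
      tags[[key]] <- val
      if (key == "0002,0010") ts <- dcm_string(val)
      if (key == "7FE0,0010") break
    }
    pos <- vstart + len
  }
  tags
}

dcm_string <- function(val) {
  trimws(rawToChar(val[val != as.raw(0L)]))
}

dcm_ds <- function(tags, key, default = NULL) {
  if (is.null(tags[[key]])) return(default)
  as.double(strsplit(dcm_string(tags[[key]]), "\\\\")[[1]])
}
dcm_us <- function(tags, key, default = NULL) {
  if (is.null(tags[[key]])) return(default)
  dcm_u16(tags[[key]], 1L)
}

#' Read a DICOM CT series as a volume
#'
#' Parses every DICOM file in `dir`, sorts the slices by the projection of
#' their position onto the slice normal (the cross product of the row and
#' column direction cosines), checks slice-spacing uniformity within 10% of
#' the median gap, and applies the rescale slope/intercept so values are CT
#' numbers.  Only uncompressed little-endian transfer syntaxes are handled.
#'
#' @param dir Directory containing one series.
#' @return A [voxel_grid()]; in-plane spacing from Pixel Spacing
#'   (column, row), slice spacing from the sorted positions, origin from the
#'   first slice position.
#' @export
read_dicom_series <- function(dir) {
  files <- list.files(dir, full.names = TRUE)
  files <- files[!dir.exists(files)]
  if (length(files) == 0L)
    stop("no files in DICOM directory: ", dir, call. = FALSE)
  slices <- lapply(files, parse_dicom_file)

  first <- slices[[1]]
  rows <- dcm_us(first, "0028,0010")
  cols <- dcm_us(first, "0028,0011")
  psp <- dcm_ds(first, "0028,0030", c(1, 1)) # (row spacing, column spacing)
  iop <- dcm_ds(first, "0020,0037", c(1, 0, 0, 0, 1, 0))
  if (is.null(rows) || is.null(cols))
    stop("DICOM series missing Rows/Columns", call. = FALSE)
  normal <- c(iop[2] * iop[6] - iop[3] * iop[5],
              iop[3] * iop[4] - iop[1] * iop[6],
              iop[1] * iop[5] - iop[2] * iop[4])
  ipp <- t(vapply(slices, function(s) dcm_ds(s, "0020,0032", c(0, 0, 0)), numeric(3)))
  proj <- as.vector(ipp %*% normal)
  ord <- order(proj)
  slices <- slices[ord]
  proj <- proj[ord]
  nz <- length(slices)
  if (nz > 1L) {
    gaps <- diff(proj)
    med <- median(gaps)
    if (med <= 0 || any(abs(gaps - med) > 0.1 * med))
      stop("inconsistent DICOM slice spacing (gaps ",
           paste(sprintf("%.4g", gaps), collapse = ", "),
           " exceed the 10% uniformity tolerance)", call. = FALSE)
    zsp <- med
  } else zsp <- 1
  bits <- dcm_us(first, "0028,0100", 16L)
  signed <- isTRUE(dcm_us(first, "0028,0103", 0L) == 1L)
  slope <- dcm_ds(first, "0028,1053", 1)[1]
  inter <- dcm_ds(first, "0028,1052", 0)[1]

  vals <- array(0, c(cols, rows, nz))
  for (k in seq_len(nz)) {
    px <- slices[[k]][["7FE0,0010"]]
    if (is.null(px)) stop("DICOM slice without pixel data", call. = FALSE)
    if (bits == 16L) {
      v <- readBin(px, "integer", n = rows * cols, size = 2L,
                   signed = signed, endian = "little")
    } else if (bits == 8L) {
      v <- readBin(px, "integer", n = rows * cols, size = 1L, signed = signed)
    } else stop("unsupported DICOM bit depth: ", bits, call. = FALSE)
    if (length(v) != rows * cols)
      stop("DICOM pixel data size mismatch", call. = FALSE)
    # pixel data is row-major: columns (x) fastest
    vals[, , k] <- v * slope + inter
  }
  voxel_grid(vals, c(psp[2], psp[1], zsp), origin = ipp[ord[1], ])
}
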