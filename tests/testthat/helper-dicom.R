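# Minimal explicit-VR little-endian DICOM writer used to build test series
# fixtures in code (no binary files in the repository).

.u16 <- function(x) writeBin(as.integer(x), raw(), size = 2, endian = "little")
.u32 <- function(x) writeBin(as.integer(x), raw(), size = 4, endian = "little")

dcm_elem <- function(group, elem, vr, value) {
  if (is.character(value)) {
    v <- charToRaw(value)
    pad <- if (vr == "UI") as.raw(0L) else charToRaw(" ")
    if (length(v) %% 2 == 1) v <- c(v, pad)
  } else v <- value
  long <- vr %in% c("OB", "OW", "OF", "SQ", "UT", "UN")
  c(.u16(group), .u16(elem), charToRaw(vr),
    if (long) c(as.raw(c(0, 0)), .u32(length(v))) else .u16(length(v)),
    v)
}

write_test_dicom_slice <- function(path, pixels_int16, rows, cols, ipp,
                                   iop = c(1, 0, 0, 0, 1, 0),
                                   pixel_spacing = c(1, 1),
                                   slope = 1, intercept = 0) {
  meta <- dcm_elem(0x0002, 0x0010, "UI", "1.2.840.10008.1.2.1")
  meta <- c(dcm_elem(0x0002, 0x0000, "UL", .u32(length(meta))), meta)
  px <- writeBin(as.integer(pixels_int16), raw(), size = 2, endian = "little")
  ds <- c(
    dcm_elem(0x0008, 0x0060, "CS", "CT"),
    dcm_elem(0x0020, 0x0032, "DS", paste(ipp, collapse = "\\")),
    dcm_elem(0x0020, 0x0037, "DS", paste(iop, collapse = "\\")),
    dcm_elem(0x0028, 0x0010, "US", .u16(rows)),
    dcm_elem(0x0028, 0x0011, "US", .u16(cols)),
    dcm_elem(0x0028, 0x0030, "DS", paste(pixel_spacing, collapse = "\\")),
    dcm_elem(0x0028, 0x0100, "US", .u16(16)),
    dcm_elem(0x0028, 0x0103, "US", .u16(1)),
    dcm_elem(0x0028, 0x1052, "DS", as.character(intercept)),
    dcm_elem(0x0028, 0x1053, "DS", as.character(slope)),
    dcm_elem(0x7FE0, 0x0010, "OW", px))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(raw(128), charToRaw("DICM"), meta, ds), con)
}

# Write a whole synthetic series (x fastest in `arr`).
write_test_dicom_series <- function(dir, arr, pixel_spacing = c(1, 1),
                                    slice_gap = 1, slope = 1, intercept = 0,
                                    names = NULL) {
  d <- dim(arr)
  if (is.null(names)) names <- sprintf("slice_%03d.dcm", seq_len(d[3]))
  for (k in seq_len(d[3]))
    write_test_dicom_slice(file.path(dir, names[k]),
                           as.vector(arr[, , k]), rows = d[2], cols = d[1],
                           ipp = c(0, 0, (k - 1) * slice_gap),
                           pixel_spacing = pixel_spacing,
                           slope = slope, intercept = intercept)
  invisible(file.path(dir, names))
}
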