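# Mesh IO: PLY (binary little-endian, the default interchange format of the
# virtual-anthropology toolchain), binary STL and OBJ.  Coordinates are
# written in physical millimetres.  Readers cover what the writers emit (plus
# ASCII PLY), enough for round-trips and for meshcheck on existing files.

guess_mesh_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("ply", "stl", "obj")) return(ext)
  stop("cannot infer mesh format from path: ", path, call. = FALSE)
}

#' Write a triangle mesh
#'
#' Validates the mesh (nonempty, indices in range, no degenerate faces)
#' before writing; a validation failure aborts without touching the file.
#' PLY output is binary little-endian and byte-deterministic.
#'
#' @param mesh A [tri_mesh()].
#' @param path Output path.
#' @param format `"auto"` (from extension), `"ply"`, `"stl"` or `"obj"`.
#' @return Invisibly, `path`.
#' @export
write_mesh <- function(mesh, path, format = c("auto", "ply", "stl", "obj")) {
  format <- match.arg(format)
  if (format == "auto") format <- guess_mesh_format(path)
  stopifnot(inherits(mesh, "tri_mesh"))
  V <- mesh$vertices
  F <- mesh$faces
  if (nrow(V) == 0L || nrow(F) == 0L)
    stop("refusing to write an empty mesh", call. = FALSE)
  if (min(F) < 1L || max(F) > nrow(V))
    stop("mesh face indices out of range", call. = FALSE)
  if (any(F[, 1] == F[, 2] | F[, 1] == F[, 3] | F[, 2] == F[, 3]))
    stop("mesh contains degenerate faces", call. = FALSE)
  switch(format,
         ply = write_ply(V, F, path),
         stl = write_stl(V, F, path),
         obj = write_obj(V, F, path))
  invisible(path)
}

#' Read a triangle mesh
#'
#' @param path `.ply` (binary little-endian or ASCII), `.stl` (binary) or
#'   `.obj` file.
#' @param format `"auto"` or an explicit format.
#' @return A [tri_mesh()].  STL facets are de-duplicated into indexed
#'   vertices by exact coordinate match.
#' @export
read_mesh <- function(path, format = c("auto", "ply", "stl", "obj")) {
  format <- match.arg(format)
  if (format == "auto") format <- guess_mesh_format(path)
  if (!file.exists(path)) stop("mesh file not found: ", path, call. = FALSE)
  switch(format,
         ply = read_ply(path),
         stl = read_stl(path),
         obj = read_obj(path))
}

# ---- PLY -------------------------------------------------------------------

write_ply <- function(V, F, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- c("ply",
           "format binary_little_endian 1.0",
           "comment endocranial surface (mm)",
           sprintf("element vertex %d", nrow(V)),
           "property float x", "property float y", "property float z",
           sprintf("element face %d", nrow(F)),
           "property list uchar int vertex_indices",
           "end_header")
  writeChar(paste0(paste(hdr, collapse = "\n"), "\n"), con, eos = NULL)
  writeBin(as.vector(t(V)), con, size = 4L, endian = "little")
  idx <- writeBin(as.integer(t(F) - 1L), raw(), size = 4L, endian = "little")
  rec <- rbind(matrix(as.raw(3L), nrow = 1, ncol = nrow(F)),
               matrix(idx, nrow = 12L))
  writeBin(as.vector(rec), con)
}

read_ply <- function(path) {
  bytes <- readBin(path, "raw", file.size(path))
  hdr_pos <- grepRaw("end_header\n", bytes, fixed = TRUE)
  if (length(hdr_pos) == 0L) stop("malformed PLY: no end_header", call. = FALSE)
  hdr_bytes <- hdr_pos[1] + nchar("end_header\n") - 1L
  hdr <- strsplit(rawToChar(bytes[seq_len(hdr_bytes)]), "\n")[[1]]
  if (hdr[1] != "ply") stop("not a PLY file: ", path, call. = FALSE)
  fmt <- sub("^format ", "", grep("^format ", hdr, value = TRUE)[1])
  nv <- as.integer(sub("^element vertex ", "",
                       grep("^element vertex ", hdr, value = TRUE)[1]))
  nf <- as.integer(sub("^element face ", "",
                       grep("^element face ", hdr, value = TRUE)[1]))
  if (grepl("^ascii", fmt)) {
    lines <- strsplit(rawToChar(bytes), "\n")[[1]]
    body <- lines[(length(hdr) + 1L):length(lines)]
    vl <- body[seq_len(nv)]
    V <- do.call(rbind, lapply(strsplit(trimws(vl), "\\s+"),
                               function(x) as.double(x[1:3])))
    fl <- body[nv + seq_len(nf)]
    F <- do.call(rbind, lapply(strsplit(trimws(fl), "\\s+"), function(x) {
      cnt <- as.integer(x[1])
      if (cnt != 3L) stop("only triangle PLY faces supported", call. = FALSE)
      as.integer(x[2:4]) + 1L
    }))
    return(tri_mesh(V, F))
  }
  if (!grepl("^binary_little_endian", fmt))
    stop("unsupported PLY format: ", fmt, call. = FALSE)
  # only the vertex/face layout written by write_ply is supported
  vprops <- grep("^property ", hdr, value = TRUE)
  if (!all(c("property float x", "property float y", "property float z") %in% vprops))
    stop("unsupported binary PLY vertex layout", call. = FALSE)
  off <- hdr_bytes
  V <- matrix(readBin(bytes[(off + 1L):(off + 12L * nv)], "numeric",
                      n = 3L * nv, size = 4L, endian = "little"),
              ncol = 3L, byrow = TRUE)
  off <- off + 12L * nv
  rec <- matrix(bytes[(off + 1L):(off + 13L * nf)], nrow = 13L)
  counts <- as.integer(rec[1L, ])
  if (any(counts != 3L)) stop("only triangle PLY faces supported", call. = FALSE)
  F <- matrix(readBin(as.vector(rec[2:13, , drop = FALSE]), "integer",
                      n = 3L * nf, size = 4L, endian = "little"),
              ncol = 3L, byrow = TRUE) + 1L
  tri_mesh(V, F)
}

# ---- STL (binary) ----------------------------------------------------------

write_stl <- function(V, F, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- charToRaw("endocast binary STL")
  writeBin(c(hdr, raw(80L - length(hdr))), con)
  writeBin(as.integer(nrow(F)), con, size = 4L, endian = "little")
  a <- V[F[, 1], , drop = FALSE]
  b <- V[F[, 2], , drop = FALSE]
  c_ <- V[F[, 3], , drop = FALSE]
  n <- cbind((b[, 2] - a[, 2]) * (c_[, 3] - a[, 3]) - (b[, 3] - a[, 3]) * (c_[, 2] - a[, 2]),
             (b[, 3] - a[, 3]) * (c_[, 1] - a[, 1]) - (b[, 1] - a[, 1]) * (c_[, 3] - a[, 3]),
             (b[, 1] - a[, 1]) * (c_[, 2] - a[, 2]) - (b[, 2] - a[, 2]) * (c_[, 1] - a[, 1]))
  len <- sqrt(rowSums(n^2))
  len[len == 0] <- 1
  n <- n / len
  block <- t(cbind(n, a, b, c_)) # 12 floats per facet
  fb <- writeBin(as.vector(block), raw(), size = 4L, endian = "little")
  rec <- rbind(matrix(fb, nrow = 48L), matrix(as.raw(0L), nrow = 2L, ncol = nrow(F)))
  writeBin(as.vector(rec), con)
}

read_stl <- function(path) {
  bytes <- readBin(path, "raw", file.size(path))
  if (length(bytes) < 84L) stop("malformed STL: too short", call. = FALSE)
  nf <- readBin(bytes[81:84], "integer", size = 4L, endian = "little")
  need <- 84L + 50L * nf
  if (length(bytes) < need) stop("malformed STL: truncated", call. = FALSE)
  rec <- matrix(bytes[85:need], nrow = 50L)
  fl <- matrix(readBin(as.vector(rec[1:48, , drop = FALSE]), "numeric",
                       n = 12L * nf, size = 4L, endian = "little"),
               nrow = 12L)
  verts <- matrix(as.vector(fl[4:12, , drop = FALSE]), ncol = 3L, byrow = TRUE)
  key <- apply(verts, 1, paste, collapse = ",")
  uid <- !duplicated(key)
  V <- verts[uid, , drop = FALSE]
  F <- matrix(match(key, key[uid]), ncol = 3L, byrow = TRUE)
  tri_mesh(V, F)
}

# ---- OBJ -------------------------------------------------------------------

write_obj <- function(V, F, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("# endocranial surface (mm)\n", con, eos = NULL)
  writeChar(paste0(sprintf("v %.9g %.9g %.9g", V[, 1], V[, 2], V[, 3]),
                   collapse = "\n"), con, eos = NULL)
  writeChar("\n", con, eos = NULL)
  writeChar(paste0(sprintf("f %d %d %d", F[, 1], F[, 2], F[, 3]),
                   collapse = "\n"), con, eos = NULL)
  writeChar("\n", con, eos = NULL)
}

read_obj <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vl <- grep("^v ", lines, value = TRUE)
  fl <- grep("^f ", lines, value = TRUE)
  V <- do.call(rbind, lapply(strsplit(trimws(sub("^v", "", vl)), "\\s+"),
                             function(x) as.double(x[x != ""][1:3])))
  F <- do.call(rbind, lapply(strsplit(trimws(sub("^f", "", fl)), "\\s+"),
                             function(x) {
                               x <- x[x != ""]
                               as.integer(sub("/.*", "", x[1:3]))
                             }))
  tri_mesh(V, F)
}
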