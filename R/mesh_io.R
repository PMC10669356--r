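# Surface-mesh file IO: STL (ascii and binary) and PLY (ascii).
# STL files carry no connectivity, so vertices are merged on read by
# coordinate (round-trip safe at 1e-9 mm).

#' Write a triangle surface to STL or PLY
#'
#' @param s a `tri_surface`.
#' @param path output file; format chosen by extension (`.stl`, `.ply`)
#'   unless `format` is given.
#' @param format `"stl"` or `"ply"`.
#' @param binary write binary STL instead of ascii (ignored for PLY).
#' @return `path`, invisibly.
#' @export
write_surface <- function(s, path, format = NULL, binary = FALSE) {
  format <- format %||% tolower(tools::file_ext(path))
  switch(format,
         stl = if (binary) write_stl_binary(s, path) else write_stl_ascii(s, path),
         ply = write_ply_ascii(s, path),
         stop("unsupported surface format '", format, "'"))
  invisible(path)
}

#' Read a triangle surface from STL or PLY
#'
#' @param path input file (`.stl` ascii or binary, `.ply` ascii).
#' @return a `tri_surface`.
#' @export
read_surface <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         stl = read_stl(path),
         ply = read_ply_ascii(path),
         stop("unsupported surface format '", ext, "'"))
}

face_normals_unit <- function(s) {
  fc <- face_corners(s)
  n <- cross3(fc$b - fc$a, fc$c - fc$a)
  len <- sqrt(rowSums(n^2)); len[len == 0] <- 1
  n / len
}

write_stl_ascii <- function(s, path) {
  n <- face_normals_unit(s)
  fc <- face_corners(s)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("solid periofem", con)
  body <- sprintf(
    paste0("facet normal %.9g %.9g %.9g\n outer loop\n",
           "  vertex %.9g %.9g %.9g\n  vertex %.9g %.9g %.9g\n",
           "  vertex %.9g %.9g %.9g\n endloop\nendfacet"),
    n[, 1], n[, 2], n[, 3],
    fc$a[, 1], fc$a[, 2], fc$a[, 3],
    fc$b[, 1], fc$b[, 2], fc$b[, 3],
    fc$c[, 1], fc$c[, 2], fc$c[, 3])
  writeLines(body, con)
  writeLines("endsolid periofem", con)
}

write_stl_binary <- function(s, path) {
  n <- face_normals_unit(s)
  fc <- face_corners(s)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.raw(rep(0L, 80)), con)
  writeBin(as.integer(nrow(s$faces)), con, size = 4, endian = "little")
  tri <- t(cbind(n, fc$a, fc$b, fc$c))          # 12 floats per facet, column-wise
  for (k in seq_len(nrow(s$faces))) {
    writeBin(as.numeric(tri[, k]), con, size = 4, endian = "little")
    writeBin(as.integer(0), con, size = 2, endian = "little")
  }
}

merge_stl_vertices <- function(tri) {
  # tri: (3m) x 3 matrix of corner coordinates, rows abcabc...
  key <- paste(sprintf("%.9f", tri[, 1]), sprintf("%.9f", tri[, 2]),
               sprintf("%.9f", tri[, 3]))
  idx <- match(key, unique(key))
  verts <- tri[!duplicated(key), , drop = FALSE]
  faces <- matrix(idx, ncol = 3, byrow = TRUE)
  tri_surface(verts, faces)
}

read_stl <- function(path) {
  head <- readBin(path, "raw", n = 6)
  if (identical(rawToChar(head[1:5]), "solid")) {
    txt <- readLines(path, warn = FALSE)
    vl <- grep("^\\s*vertex", txt, value = TRUE)
    nums <- do.call(rbind, lapply(strsplit(trimws(vl), "\\s+"), function(x)
      as.numeric(x[2:4])))
    if (nrow(nums) %% 3 != 0) stop("malformed ascii STL: ", path)
    return(merge_stl_vertices(nums))
  }
  con <- file(path, "rb")
  on.exit(close(con))
  invisible(readBin(con, "raw", n = 80))
  m <- readBin(con, "integer", n = 1, size = 4, endian = "little")
  tri <- matrix(NA_real_, 3 * m, 3)
  for (k in seq_len(m)) {
    vals <- readBin(con, "numeric", n = 12, size = 4, endian = "little")
    readBin(con, "integer", n = 1, size = 2, endian = "little")
    tri[(3 * k - 2):(3 * k), ] <- matrix(vals[4:12], 3, 3, byrow = TRUE)
  }
  merge_stl_vertices(tri)
}

write_ply_ascii <- function(s, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               sprintf("element vertex %d", nrow(s$vertices)),
               "property double x", "property double y", "property double z",
               sprintf("element face %d", nrow(s$faces)),
               "property list uchar int vertex_indices", "end_header"), con)
  writeLines(sprintf("%.12g %.12g %.12g",
                     s$vertices[, 1], s$vertices[, 2], s$vertices[, 3]), con)
  writeLines(sprintf("3 %d %d %d",
                     s$faces[, 1] - 1L, s$faces[, 2] - 1L, s$faces[, 3] - 1L), con)
}

read_ply_ascii <- function(path) {
  txt <- readLines(path, warn = FALSE)
  if (txt[1] != "ply" || !grepl("ascii", txt[2]))
    stop("only ascii PLY supported: ", path)
  nv <- as.integer(sub("element vertex ", "", grep("^element vertex", txt, value = TRUE)))
  nf <- as.integer(sub("element face ", "", grep("^element face", txt, value = TRUE)))
  start <- which(txt == "end_header") + 1L
  vline <- txt[start:(start + nv - 1L)]
  verts <- do.call(rbind, lapply(strsplit(trimws(vline), "\\s+"), function(x)
    as.numeric(x[1:3])))
  fline <- txt[(start + nv):(start + nv + nf - 1L)]
  faces <- do.call(rbind, lapply(strsplit(trimws(fline), "\\s+"), function(x) {
    if (as.integer(x[1]) != 3L) stop("non-triangular face in ", path)
    as.integer(x[2:4]) + 1L
  }))
  tri_surface(verts, faces)
}
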