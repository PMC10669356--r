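# Ascii VTU (VTK unstructured-grid XML) export and read-back for meshes and
# fields.  Cell types: 10 = linear tetra, 24 = quadratic tetra.

#' Write a mesh (with optional fields) to an ascii VTU file
#'
#' @param mesh an `fe_mesh`.
#' @param path output file.
#' @param point_data named list of per-node vectors or `n x k` matrices.
#' @param cell_data named list of per-element vectors.
#' @return `path`, invisibly.
#' @export
write_vtu <- function(mesh, path, point_data = list(), cell_data = list()) {
  n <- nrow(mesh$nodes); m <- nrow(mesh$elems)
  nn <- ncol(mesh$elems)
  ctype <- if (nn == 10L) 24L else 10L
  num <- function(x) paste(sprintf("%.17g", x), collapse = " ")
  da <- function(name, x, comps = NULL) {
    x <- as.matrix(x)
    comps <- comps %||% ncol(x)
    sprintf('<DataArray type="Float64" Name="%s" NumberOfComponents="%d" format="ascii">\n%s\n</DataArray>',
            name, comps, num(t(x)))
  }
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(c(...), con)
  w('<?xml version="1.0"?>',
    '<VTKFile type="UnstructuredGrid" version="0.1" byte_order="LittleEndian">',
    '<UnstructuredGrid>',
    sprintf('<Piece NumberOfPoints="%d" NumberOfCells="%d">', n, m))
  w('<Points>', da("Points", mesh$nodes, 3L), '</Points>')
  w('<Cells>',
    sprintf('<DataArray type="Int64" Name="connectivity" format="ascii">\n%s\n</DataArray>',
            paste(t(mesh$elems) - 1L, collapse = " ")),
    sprintf('<DataArray type="Int64" Name="offsets" format="ascii">\n%s\n</DataArray>',
            paste(seq_len(m) * nn, collapse = " ")),
    sprintf('<DataArray type="UInt8" Name="types" format="ascii">\n%s\n</DataArray>',
            paste(rep(ctype, m), collapse = " ")),
    '</Cells>')
  if (length(point_data)) {
    w('<PointData>')
    for (nmx in names(point_data)) w(da(nmx, point_data[[nmx]]))
    w('</PointData>')
  }
  if (length(cell_data)) {
    w('<CellData>')
    for (nmx in names(cell_data)) w(da(nmx, cell_data[[nmx]]))
    w('</CellData>')
  }
  w('</Piece>', '</UnstructuredGrid>', '</VTKFile>')
  invisible(path)
}

#' Read an ascii VTU file written by [write_vtu()]
#'
#' @param path VTU file.
#' @return list with `nodes`, `elems`, `point_data`, `cell_data`.
#' @export
read_vtu <- function(path) {
  doc <- xml2::read_xml(path)
  piece <- xml2::xml_find_first(doc, ".//Piece")
  getarr <- function(node) {
    vals <- as.numeric(strsplit(trimws(xml2::xml_text(node)), "\\s+")[[1]])
    vals
  }
  pts <- xml2::xml_find_first(piece, ".//Points/DataArray")
  nodes <- matrix(getarr(pts), ncol = 3, byrow = TRUE)
  conn <- getarr(xml2::xml_find_first(piece, ".//Cells/DataArray[@Name='connectivity']"))
  off <- getarr(xml2::xml_find_first(piece, ".//Cells/DataArray[@Name='offsets']"))
  nn <- off[1]
  elems <- matrix(as.integer(conn) + 1L, ncol = nn, byrow = TRUE)
  read_block <- function(xpath) {
    out <- list()
    for (nd in xml2::xml_find_all(piece, xpath)) {
      nmx <- xml2::xml_attr(nd, "Name")
      k <- as.integer(xml2::xml_attr(nd, "NumberOfComponents"))
      v <- getarr(nd)
      out[[nmx]] <- if (!is.na(k) && k > 1) matrix(v, ncol = k, byrow = TRUE) else v
    }
    out
  }
  list(nodes = nodes, elems = elems,
       point_data = read_block(".//PointData/DataArray"),
       cell_data = read_block(".//CellData/DataArray"))
}
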