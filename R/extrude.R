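# Prism extrusion and tetrahedralization utilities.
#
# All volume meshes in the package are built by extruding a fixed 2D triangle
# template through a stack of z-planes and splitting each triangular prism
# into three tetrahedra.  The diagonal of every quadrilateral prism face is
# chosen by the minimum-global-vertex rule, which makes the choice identical
# for the two prisms sharing the face, so the resulting tetrahedral mesh is
# conforming by construction.

# prisms: N x 6 integer matrix (bottom triangle CCW from above, then top).
# Returns list(tets = 3N x 4, prism = prism row index per tet).
split_prisms <- function(prisms) {
  stopifnot(ncol(prisms) == 6)
  M <- prisms
  amin <- max.col(-M, ties.method = "first")
  # bring the smallest global vertex into the bottom triangle
  flip <- amin > 3L
  if (any(flip)) {
    M[flip, ] <- M[flip, c(4L, 6L, 5L, 1L, 3L, 2L), drop = FALSE]
    amin[flip] <- c(1L, 3L, 2L)[amin[flip] - 3L]
  }
  # rotate the bottom triangle so the smallest vertex sits at position 1
  r2 <- amin == 2L
  if (any(r2)) M[r2, ] <- M[r2, c(2L, 3L, 1L, 5L, 6L, 4L), drop = FALSE]
  r3 <- amin == 3L
  if (any(r3)) M[r3, ] <- M[r3, c(3L, 1L, 2L, 6L, 4L, 5L), drop = FALSE]
  # split the remaining quad (V2,V3,V6,V5) through its smallest vertex
  caseA <- pmin(M[, 2], M[, 6]) < pmin(M[, 3], M[, 5])
  n <- nrow(M)
  tets <- matrix(0L, 3L * n, 4L)
  idx <- seq_len(n)
  a <- which(caseA); b <- which(!caseA)
  tets[3 * a - 2, ] <- M[a, c(1L, 2L, 3L, 6L), drop = FALSE]
  tets[3 * a - 1, ] <- M[a, c(1L, 2L, 6L, 5L), drop = FALSE]
  tets[3 * b - 2, ] <- M[b, c(1L, 2L, 3L, 5L), drop = FALSE]
  tets[3 * b - 1, ] <- M[b, c(1L, 3L, 6L, 5L), drop = FALSE]
  tets[3 * idx, ] <- M[, c(1L, 5L, 6L, 4L), drop = FALSE]
  list(tets = tets, prism = rep(idx, each = 3L))
}

# VTK tetra edge order: (1,2) (2,3) (1,3) (1,4) (2,4) (3,4)
TET_EDGES <- rbind(c(1L, 2L), c(2L, 3L), c(1L, 3L),
                   c(1L, 4L), c(2L, 4L), c(3L, 4L))

edge_key <- function(a, b) {
  lo <- pmin(a, b); hi <- pmax(a, b)
  lo * 2097152 + hi          # valid while node count < 2^21
}

# Insert midside nodes; returns list(nodes, elems10, key, mid_id) where key /
# mid_id map corner-node pairs to midside node ids.
add_midside_nodes <- function(nodes, tets) {
  n0 <- nrow(nodes)
  keys <- matrix(0, nrow(tets), 6L)
  for (e in 1:6)
    keys[, e] <- edge_key(tets[, TET_EDGES[e, 1]], tets[, TET_EDGES[e, 2]])
  uk <- unique(as.vector(keys))
  mid_of <- n0 + seq_along(uk)
  lo <- floor(uk / 2097152); hi <- uk - lo * 2097152
  mids <- (nodes[lo, , drop = FALSE] + nodes[hi, , drop = FALSE]) / 2
  elems10 <- cbind(tets, matrix(0L, nrow(tets), 6L))
  for (e in 1:6)
    elems10[, 4L + e] <- mid_of[match(keys[, e], uk)]
  list(nodes = rbind(nodes, mids), elems = elems10, key = uk, mid_id = mid_of)
}

midside_lookup <- function(mesh, a, b) {
  if (is.null(mesh$edge_key)) return(NULL)
  mesh$mid_id[match(edge_key(a, b), mesh$edge_key)]
}

# Outward-oriented local faces of a positively oriented tetrahedron.
TET_FACES <- rbind(c(1L, 3L, 2L), c(1L, 2L, 4L), c(2L, 3L, 4L), c(1L, 4L, 3L))

# All element faces with adjacency.  Returns a data.table with oriented
# corners (outward from elem1), owner elem1/region1 and, for interior faces,
# elem2/region2.
face_adjacency <- function(tets, region) {
  m <- nrow(tets)
  f <- rbind(tets[, TET_FACES[1, ]], tets[, TET_FACES[2, ]],
             tets[, TET_FACES[3, ]], tets[, TET_FACES[4, ]])
  elem <- rep.int(seq_len(m), 4L)
  k1 <- pmin(f[, 1], f[, 2], f[, 3])
  k3 <- pmax(f[, 1], f[, 2], f[, 3])
  k2 <- as.integer(as.numeric(f[, 1]) + f[, 2] + f[, 3] - k1 - k3)
  dt <- data.table::data.table(k1 = k1, k2 = k2, k3 = k3,
                               a = f[, 1], b = f[, 2], c = f[, 3],
                               elem = elem, region = region[elem])
  data.table::setkeyv(dt, c("k1", "k2", "k3"))
  idx <- dt[, .I[1], by = c("k1", "k2", "k3")]  # representative per face
  cnt <- dt[, .N, by = c("k1", "k2", "k3")]
  if (any(cnt$N > 2L)) stop("non-manifold face detected")
  second <- dt[, if (.N == 2L) .I[2] else NA_integer_, by = c("k1", "k2", "k3")]
  out <- dt[idx$V1, .(a, b, c, elem1 = elem, region1 = region)]
  out[, `:=`(elem2 = dt$elem[second$V1], region2 = dt$region[second$V1])]
  # keep the second side's orientation handy for interface sets
  out[, `:=`(a2 = dt$a[second$V1], b2 = dt$b[second$V1], c2 = dt$c[second$V1])]
  out[]
}

# Compact node numbering to used nodes only.
compact_nodes <- function(nodes, tets) {
  used <- sort(unique(as.vector(tets)))
  remap <- integer(nrow(nodes))
  remap[used] <- seq_along(used)
  list(nodes = nodes[used, , drop = FALSE],
       tets = matrix(remap[tets], ncol = ncol(tets)),
       used = used)
}

# Facet-set constructor: oriented corner triples + owner elements (+ midside
# ids on quadratic meshes).
make_facet_set <- function(corners, elem, mesh) {
  mid <- NULL
  if (mesh$order == 2L) {
    mid <- cbind(midside_lookup(mesh, corners[, 1], corners[, 2]),
                 midside_lookup(mesh, corners[, 2], corners[, 3]),
                 midside_lookup(mesh, corners[, 3], corners[, 1]))
  }
  list(corners = corners, elem = as.integer(elem), mid = mid)
}

#' Facet geometry of a named facet set
#'
#' @param mesh an `fe_mesh`.
#' @param set facet-set name (e.g. `"pdl_bone_interface"`).
#' @return list with `centroid` (f x 3), unit `normal` (f x 3, oriented as
#'   stored: outward from the owner element), `area` (mm^2) and owner
#'   `elem` ids.
#' @export
facet_geometry <- function(mesh, set) {
  fs <- mesh$facet_sets[[set]]
  if (is.null(fs)) stop("no facet set '", set, "'; available: ",
                        paste(names(mesh$facet_sets), collapse = ", "))
  a <- mesh$nodes[fs$corners[, 1], , drop = FALSE]
  b <- mesh$nodes[fs$corners[, 2], , drop = FALSE]
  c_ <- mesh$nodes[fs$corners[, 3], , drop = FALSE]
  n <- cross3(b - a, c_ - a)
  len <- sqrt(rowSums(n^2))
  list(centroid = (a + b + c_) / 3, normal = n / len, area = len / 2,
       elem = fs$elem)
}
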