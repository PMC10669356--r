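# Volume meshing of layered tooth models and verification blocks.

REGIONS <- c("enamel", "dentin", "pulp", "cementum", "pdl",
             "cortical_bone", "cancellous_bone", "gingiva")
BONE_REGIONS <- c("cortical_bone", "cancellous_bone")
PDL_CAP_CEM <- 0.15   # apical cementum cap thickness (mm)
PDL_CAP <- 0.10       # apical ligament cap thickness (mm)
ROOF_PDL <- 0.10      # furcation-roof ligament thickness (mm)
ROOF_CEM <- 0.15      # cementum sheet covering the furcation roof (mm)
PULP_END <- 0.75      # pulp canal ends at this fraction of root length

build_planes <- function(model, size) {
  p <- model$params
  La <- p$root_length; ch <- p$crown_height; H <- p$bone_block_dims[3]
  red <- model$attachment_reduction
  nsub <- max(1L, as.integer(round(1 / size)))
  root <- seq(0, La, by = 1 / nsub)
  crown <- seq(-ch, 0, length.out = max(3L, round(ch / (1.6 * size))) + 1)
  below0 <- La + PDL_CAP_CEM + PDL_CAP
  below <- seq(below0, H, length.out = max(2L, ceiling((H - below0) / (1.8 * size))) + 1)
  # ligament layers carry two element layers through their thickness:
  # the radial shell via its two template rings, the horizontal caps and
  # the furcation roof via split slabs
  special <- c(-ch, 0, La, La + PDL_CAP_CEM, La + PDL_CAP_CEM + PDL_CAP / 2,
               below0, H)
  if (model$tooth_class == "multi_rooted") {
    furc <- p$furcation_depth_below_CEJ
    special <- c(special, furc - ROOF_CEM, furc, furc + ROOF_PDL / 2,
                 furc + ROOF_PDL)
  }
  if (red > 0 && red < La) special <- c(special, red)
  special <- sort(unique(round(special, 8)))
  regular <- sort(unique(round(c(crown, root, below), 8)))
  near <- vapply(regular, function(z) any(abs(z - special) < 0.049), TRUE)
  sort(unique(c(special, regular[!near])))
}

# Tissue label per template triangle for the slab with midpoint zc.
# "" means the triangle is absent from this slab.
slab_labels <- function(tpl, zc, model) {
  at <- tpl$attrs
  p <- model$params
  La <- p$root_length; H <- p$bone_block_dims[3]
  red <- model$attachment_reduction
  multi <- tpl$multi
  furc <- if (multi) p$furcation_depth_below_CEJ else Inf
  tcort <- p$cortical_shell_thickness
  n <- nrow(at)
  lab <- character(n)
  bone <- ifelse(at$cortical_xy | zc > H - tcort, "cortical_bone", "cancellous_bone")

  bg <- at$kind == "bg"
  sep <- bg & at$septum
  trans <- at$band %in% c("trans_a", "trans_b")
  pdlb <- at$band %in% c("pdl_a", "pdl_b")
  cem <- at$band == "cem"
  den <- at$band %in% c("den_a", "den_b")
  fan <- at$kind == "fan"
  inw <- multi & at$inward
  ging <- p$include_gingiva & zc < red & zc < 2

  if (zc < 0) {                                   # crown
    lab[trans & inw] <- "dentin"
    lab[pdlb & inw] <- "dentin"
    lab[cem] <- ifelse(inw[cem], "dentin", "enamel")
    lab[den] <- "dentin"
    lab[fan] <- "pulp"
    lab[sep] <- "dentin"
  } else if (zc <= La) {                          # root
    trunk <- inw & zc < furc                      # inter-radicular tooth web
    roof_slab <- zc >= furc & zc < furc + ROOF_PDL & red <= furc
    # free gap around the trunk web, carried through the roof slab so the
    # web and the bone never share mesh nodes (no spurious bonded contact)
    embrasure <- multi & zc < furc + ROOF_PDL
    removed <- zc < red                           # coronal to reduction plane
    gone_lab <- if (ging) "gingiva" else ""
    lab[trans] <- bone[trans]
    if (roof_slab) lab[trans & at$inward] <- "pdl"
    if (removed) lab[trans] <- gone_lab
    if (embrasure) lab[trans & at$guard] <- ""
    # trunk web: dentin, with a cementum sheet covering the furcation roof
    web_lab <- if (zc >= furc - ROOF_CEM) "cementum" else "dentin"
    lab[trans & trunk] <- web_lab
    lab[pdlb] <- if (removed) gone_lab else "pdl"
    lab[pdlb & trunk] <- web_lab
    lab[cem] <- "cementum"
    lab[cem & trunk] <- web_lab
    lab[den] <- "dentin"
    lab[fan] <- if (zc < PULP_END * La) "pulp" else "dentin"
    lab[sep] <- if (zc < furc) web_lab else if (removed) "" else
                if (roof_slab) "pdl" else NA_character_
    if (anyNA(lab[sep])) lab[sep] <- bone[sep]    # plain septal bone
    bgp <- bg & !at$septum
    lab[bgp] <- if (removed) "" else bone[bgp]
    if (embrasure) lab[bgp & at$flank] <- ""
  } else if (zc <= La + PDL_CAP_CEM) {            # apical cementum cap
    lab[trans] <- bone[trans]
    lab[pdlb] <- "pdl"
    lab[cem | den | fan] <- "cementum"
    lab[bg] <- bone[bg]
  } else if (zc <= La + PDL_CAP_CEM + PDL_CAP) {  # apical ligament cap
    lab[trans] <- bone[trans]
    lab[pdlb | cem | den | fan] <- "pdl"
    lab[bg] <- bone[bg]
  } else {                                        # basal bone
    lab[] <- bone
    lab[bg] <- bone[bg]
  }
  lab
}

#' Generate a conforming tetrahedral mesh of a tooth model
#'
#' Extrudes the layered cross-section template through a stack of z-planes
#' and splits the prisms into tetrahedra.  Every tissue interface is made of
#' shared mesh facets (bonded contact by conformity), each element carries
#' exactly one tissue tag, and the PDL shell is two elements thick through
#' its 0.1 mm thickness.  Meshing is deterministic: the same model and size
#' always give the identical mesh.
#'
#' @param model a `tooth_model` from [build_tooth()] /
#'   [reduce_attachment()].
#' @param size characteristic element size in mm (in-plane and axial);
#'   layer thicknesses are always resolved regardless of `size`.
#' @param order element order: 1 (4-node) or 2 (10-node, default).
#' @return object of class `fe_mesh` with named facet sets
#'   `pdl_bone_interface`, `pdl_root_interface`, `occlusal_patch`,
#'   `outer_bone_boundary`.
#' @export
generate_mesh <- function(model, size = 1.2, order = 2L) {
  if (inherits(model, "imported_tooth_model"))
    stop("volume meshing supports parametric models only; ",
         "rebuild with build_tooth() or use the surface tools")
  stopifnot(inherits(model, "tooth_model"))
  order <- as.integer(order)
  if (!order %in% c(1L, 2L)) stop("order must be 1 or 2")
  if (size <= 0.2 || size > 4) stop("size must lie in (0.2, 4] mm")
  p <- model$params
  tpl <- build_template(model, size)
  zs <- build_planes(model, size)
  P <- length(zs)
  NS <- tpl$NS

  nodes <- matrix(0, P * NS, 3)
  for (k in seq_len(P)) {
    xy <- template_coords(tpl, zs[k], p)
    rows <- (k - 1) * NS + seq_len(NS)
    nodes[rows, 1:2] <- xy
    nodes[rows, 3] <- zs[k]
  }

  prisms <- vector("list", P - 1)
  labels <- vector("list", P - 1)
  for (s in seq_len(P - 1)) {
    zc <- (zs[s] + zs[s + 1]) / 2
    lab <- slab_labels(tpl, zc, model)
    keep <- which(lab != "")
    if (!length(keep)) next
    t3 <- tpl$tris[keep, , drop = FALSE]
    prisms[[s]] <- cbind(t3 + (s - 1L) * NS, t3 + s * NS)
    labels[[s]] <- lab[keep]
  }
  prisms <- do.call(rbind, prisms)
  labels <- unlist(labels)
  sp <- split_prisms(prisms)
  region_chr <- labels[sp$prism]

  mesh <- finalize_mesh(nodes, sp$tets, region_chr, REGIONS, order)
  mesh$characteristic_size <- size
  mesh$model <- model
  mesh$planes <- zs

  # named facet sets
  fa <- face_adjacency(mesh$elems[, 1:4, drop = FALSE], mesh$region)
  rn <- mesh$region_names
  rid <- function(x) match(x, rn)
  pdl <- rid("pdl"); boneids <- stats::na.omit(rid(BONE_REGIONS))
  rootids <- stats::na.omit(rid("cementum"))  # the ligament-bearing root surface
  pick_pdl_side <- function(other_ids) {
    i1 <- which(fa$region1 == pdl & fa$region2 %in% other_ids)
    i2 <- which(fa$region2 == pdl & fa$region1 %in% other_ids)
    corners <- rbind(as.matrix(fa[i1, c("a", "b", "c")]),
                     as.matrix(fa[i2, c("a2", "b2", "c2")]))
    make_facet_set(corners, c(fa$elem1[i1], fa$elem2[i2]), mesh)
  }
  mesh$facet_sets <- list()
  mesh$facet_sets$pdl_bone_interface <- pick_pdl_side(boneids)
  mesh$facet_sets$pdl_root_interface <- pick_pdl_side(rootids)

  bnd <- which(is.na(fa$elem2))
  bz <- matrix(mesh$nodes[as.matrix(fa[bnd, c("a", "b", "c")]), 3], ncol = 3)
  bx <- matrix(mesh$nodes[as.matrix(fa[bnd, c("a", "b", "c")]), 1], ncol = 3)
  by <- matrix(mesh$nodes[as.matrix(fa[bnd, c("a", "b", "c")]), 2], ncol = 3)
  tol <- 1e-7
  occl <- bnd[rowSums(abs(bz + p$crown_height) < tol) == 3]
  W2 <- p$bone_block_dims[1] / 2; D2 <- p$bone_block_dims[2] / 2
  H <- p$bone_block_dims[3]
  outer <- bnd[rowSums(abs(abs(bx) - W2) < tol) == 3 |
               rowSums(abs(abs(by) - D2) < tol) == 3 |
               rowSums(abs(bz - H) < tol) == 3]
  mesh$facet_sets$occlusal_patch <-
    make_facet_set(as.matrix(fa[occl, c("a", "b", "c")]), fa$elem1[occl], mesh)
  mesh$facet_sets$outer_bone_boundary <-
    make_facet_set(as.matrix(fa[outer, c("a", "b", "c")]), fa$elem1[outer], mesh)

  # CEJ ring node positions (on the root surface at z = 0)
  k0 <- which(abs(zs) < 1e-12)
  cej <- do.call(rbind, lapply(tpl$ports, function(po) {
    ids <- (k0 - 1) * NS + po$ring_ids[match("cemo", RING_NAMES), ]
    mesh$nodes[mesh$node_remap[ids], , drop = FALSE]
  }))
  mesh$cej_curve <- cej
  mesh$furcation_roof <- furcation_roof_point(model)

  nsub <- max(1L, as.integer(round(1 / size)))
  mesh$unsupported <- (p$root_length - model$attachment_reduction) < 0.999 / nsub
  class(mesh) <- "fe_mesh"
  mesh
}

# Shared mesh finalization: compact nodes, verify orientation, convert the
# character region labels to integer tags, add midside nodes for order 2.
finalize_mesh <- function(nodes, tets, region_chr, region_universe, order) {
  cn <- compact_nodes(nodes, tets)
  nodes <- cn$nodes; tets <- cn$tets
  vol <- fem_tet_volumes(nodes, tets)
  if (any(vol <= 0)) {
    bad <- which(vol <= 0)[1]
    ctr <- colMeans(nodes[tets[bad, ], , drop = FALSE])
    stop(sprintf("inverted element near (%.3f, %.3f, %.3f)",
                 ctr[1], ctr[2], ctr[3]))
  }
  region_names <- region_universe[region_universe %in% unique(region_chr)]
  extra <- setdiff(unique(region_chr), region_names)
  region_names <- c(region_names, extra)
  region <- match(region_chr, region_names)
  remap <- integer(0)
  remap[cn$used] <- seq_along(cn$used)
  mesh <- list(nodes = nodes, elems = tets, region = region,
               region_names = region_names, order = order,
               n_corner_nodes = nrow(nodes), node_remap = remap,
               volumes6 = NULL)
  if (order == 2L) {
    ms <- add_midside_nodes(nodes, tets)
    mesh$nodes <- ms$nodes
    mesh$elems <- ms$elems
    mesh$edge_key <- ms$key
    mesh$mid_id <- ms$mid_id
  }
  class(mesh) <- "fe_mesh"
  mesh
}

#' @export
print.fe_mesh <- function(x, ...) {
  cat(sprintf("<fe_mesh> %d nodes, %d tet%d elements, regions: %s\n",
              nrow(x$nodes), nrow(x$elems), if (x$order == 2L) 10 else 4,
              paste(x$region_names, collapse = ", ")))
  if (!is.null(x$facet_sets))
    cat("  facet sets:", paste(names(x$facet_sets), collapse = ", "), "\n")
  invisible(x)
}

#' Structured block mesh for verification problems
#'
#' Axis-aligned box `[0, dims]` (optionally shifted by `origin`) meshed with
#' a structured grid split into tetrahedra, with face facet sets
#' `xmin`/`xmax`/`ymin`/`ymax`/`zmin`/`zmax`.  A `region_fun(cx, cy, cz)`
#' may assign different region names per element (e.g. a bimaterial block);
#' facets between distinct regions form the `interface` set.
#'
#' @param dims box edge lengths (mm), length 3.
#' @param n subdivisions per direction, length 3.
#' @param order element order, 1 or 2.
#' @param region_fun optional vectorized function of element centroid
#'   coordinates returning region names.
#' @param origin box corner offset.
#' @return an `fe_mesh`.
#' @export
block_mesh <- function(dims = c(1, 1, 1), n = c(4, 4, 4), order = 1L,
                       region_fun = NULL, origin = c(0, 0, 0)) {
  stopifnot(length(dims) == 3, length(n) == 3, all(n >= 1))
  n <- as.integer(n)
  xs <- seq(0, dims[1], length.out = n[1] + 1) + origin[1]
  ys <- seq(0, dims[2], length.out = n[2] + 1) + origin[2]
  zs <- seq(0, dims[3], length.out = n[3] + 1) + origin[3]
  nx <- length(xs); ny <- length(ys)
  NS <- nx * ny
  id2 <- function(ix, iy) (iy - 1L) * nx + ix
  tris <- list()
  for (iy in seq_len(ny - 1)) for (ix in seq_len(nx - 1)) {
    n00 <- id2(ix, iy); n10 <- id2(ix + 1, iy)
    n11 <- id2(ix + 1, iy + 1); n01 <- id2(ix, iy + 1)
    tris[[length(tris) + 1]] <- rbind(c(n00, n10, n11), c(n00, n11, n01))
  }
  tris <- do.call(rbind, tris)
  P <- length(zs)
  nodes <- matrix(0, P * NS, 3)
  for (k in seq_len(P)) {
    rows <- (k - 1) * NS + seq_len(NS)
    nodes[rows, 1] <- rep(xs, times = ny)
    nodes[rows, 2] <- rep(ys, each = nx)
    nodes[rows, 3] <- zs[k]
  }
  prisms <- list(); labels <- list()
  for (s in seq_len(P - 1)) {
    zc <- (zs[s] + zs[s + 1]) / 2
    lab <- if (is.null(region_fun)) rep("block", nrow(tris)) else {
      a <- nodes[tris[, 1], 1:2, drop = FALSE]
      b <- nodes[tris[, 2], 1:2, drop = FALSE]
      c_ <- nodes[tris[, 3], 1:2, drop = FALSE]
      ctr <- (a + b + c_) / 3
      region_fun(ctr[, 1], ctr[, 2], rep(zc, nrow(tris)))
    }
    prisms[[s]] <- cbind(tris + (s - 1L) * NS, tris + s * NS)
    labels[[s]] <- lab
  }
  sp <- split_prisms(do.call(rbind, prisms))
  region_chr <- unlist(labels)[sp$prism]
  mesh <- finalize_mesh(nodes, sp$tets, region_chr,
                        sort(unique(region_chr)), as.integer(order))
  mesh$characteristic_size <- max(dims / n)
  fa <- face_adjacency(mesh$elems[, 1:4, drop = FALSE], mesh$region)
  bnd <- which(is.na(fa$elem2))
  co <- function(d) matrix(mesh$nodes[as.matrix(fa[bnd, c("a", "b", "c")]), d],
                           ncol = 3)
  tol <- 1e-9 * max(dims)
  lims <- list(xmin = list(1, origin[1]), xmax = list(1, origin[1] + dims[1]),
               ymin = list(2, origin[2]), ymax = list(2, origin[2] + dims[2]),
               zmin = list(3, origin[3]), zmax = list(3, origin[3] + dims[3]))
  mesh$facet_sets <- lapply(lims, function(lm) {
    sel <- bnd[rowSums(abs(co(lm[[1]]) - lm[[2]]) < tol + 1e-12) == 3]
    make_facet_set(as.matrix(fa[sel, c("a", "b", "c")]), fa$elem1[sel], mesh)
  })
  ifc <- which(!is.na(fa$elem2) & fa$region1 != fa$region2)
  if (length(ifc))
    mesh$facet_sets$interface <-
      make_facet_set(as.matrix(fa[ifc, c("a", "b", "c")]), fa$elem1[ifc], mesh)
  mesh$unsupported <- FALSE
  class(mesh) <- "fe_mesh"
  mesh
}

#' Mesh quality report
#'
#' @param mesh an `fe_mesh`.
#' @return data.frame with one row per region plus a `"total"` row:
#'   element and node counts, volume, minimum and median aspect ratio
#'   (longest edge over smallest altitude) and the minimum element Jacobian
#'   (six times the signed volume).
#' @export
mesh_quality_report <- function(mesh) {
  tets <- mesh$elems[, 1:4, drop = FALSE]
  v6 <- fem_tet_volumes(mesh$nodes, tets) * 6
  x <- lapply(1:4, function(k) mesh$nodes[tets[, k], , drop = FALSE])
  pairs <- rbind(c(1, 2), c(1, 3), c(1, 4), c(2, 3), c(2, 4), c(3, 4))
  el2 <- sapply(seq_len(6), function(e)
    rowSums((x[[pairs[e, 1]]] - x[[pairs[e, 2]]])^2))
  lmax <- sqrt(apply(el2, 1, max))
  farea <- sapply(seq_len(4), function(f) {
    ids <- TET_FACES[f, ]
    a <- x[[ids[1]]]; b <- x[[ids[2]]]; c_ <- x[[ids[3]]]
    sqrt(rowSums(cross3(b - a, c_ - a)^2)) / 2
  })
  amax <- apply(farea, 1, max)
  hmin <- (v6 / 6) * 3 / amax                 # smallest altitude
  aspect <- lmax / hmin
  per_region <- lapply(seq_along(mesh$region_names), function(r) {
    i <- mesh$region == r
    data.frame(region = mesh$region_names[r],
               n_elements = sum(i),
               n_nodes = length(unique(as.vector(mesh$elems[i, ]))),
               volume_mm3 = sum(v6[i]) / 6,
               aspect_min = min(aspect[i]), aspect_median = median(aspect[i]),
               jacobian_min = min(v6[i]))
  })
  tot <- data.frame(region = "total", n_elements = nrow(tets),
                    n_nodes = nrow(mesh$nodes),
                    volume_mm3 = sum(v6) / 6,
                    aspect_min = min(aspect), aspect_median = median(aspect),
                    jacobian_min = min(v6))
  rbind(do.call(rbind, per_region), tot)
}

#' Mesh-convergence study
#'
#' Re-runs an observable over a sequence of decreasing mesh sizes and
#' reports successive relative changes; convergence is declared when the
#' last change drops below `tol` (2 % by default, applied to the peak PDL
#' contact pressure in the default configuration).
#'
#' @param model a `tooth_model`, or a function `f(size)` returning the
#'   observable directly (for verification problems).
#' @param sizes numeric vector of at least 3 strictly decreasing mesh sizes.
#' @param observable for tooth models: `"peak_pdl_pressure"`,
#'   `"mean_pdl_pressure"`, or a function `f(mesh, solution)`.
#' @param protocol a [load_protocol()]; default per-tooth protocol.
#' @param order element order.
#' @param tol relative-change tolerance for declaring convergence.
#' @return data.frame `(size, value, rel_change)` with attributes
#'   `converged` and `tol`.
#' @export
convergence_study <- function(model, sizes, observable = "peak_pdl_pressure",
                              protocol = NULL, order = 2L, tol = 0.02) {
  if (length(sizes) < 3) stop("need at least 3 mesh sizes")
  if (any(diff(sizes) >= 0)) stop("sizes must be strictly decreasing")
  values <- if (is.function(model)) {
    vapply(sizes, model, 0)
  } else {
    protocol <- protocol %||% load_protocol()
    vapply(sizes, function(sz) {
      sol <- solve_static(model, size = sz, order = order, protocol = protocol)
      if (is.function(observable)) return(observable(sol$mesh, sol))
      pm <- contact_pressure(sol, sol$mesh)
      switch(observable,
             peak_pdl_pressure = pm$peak,
             mean_pdl_pressure = pm$mean,
             stop("unknown observable '", observable, "'"))
    }, 0)
  }
  rel <- c(NA, abs(diff(values)) / pmax(abs(values[-length(values)]), 1e-300))
  out <- data.frame(size = sizes, value = values, rel_change = rel)
  if (length(values) > 2) {
    d <- diff(values)
    if (any(d > 0) && any(d < 0) && min(rel[-1]) > tol)
      warning("observable sequence is non-monotone beyond the tolerance")
  }
  attr(out, "converged") <- rel[length(rel)] < tol
  attr(out, "tol") <- tol
  out
}
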