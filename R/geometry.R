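#' Layered tooth--PDL--bone model
#'
#' [build_tooth()] turns a [tooth_params()] description into a layered model
#' of the tooth (enamel, dentin, pulp, cementum), its periodontal ligament
#' (PDL), and the surrounding alveolar bone block (cortical shell over a
#' cancellous core).  The coordinate frame puts the origin at the CEJ
#' centroid with the root axis along +z pointing apically; the ventral
#' (transverse-load) direction is +x and the model is mirror-symmetric
#' about the y = 0 plane.
#'
#' The PDL is a uniform shell (0.1 mm by default) around the root below the
#' CEJ; the cementum between dentin and PDL is graded in three steps of
#' 50/100/150 um over the cervical/middle/apical thirds of the root.
#' Attachment loss is modelled by [reduce_attachment()], which removes the
#' PDL and the supporting bone coronal to a reduction plane perpendicular
#' to the root axis.
#'
#' @param params a [tooth_params()] object (or arguments forwarded to it).
#' @param ... forwarded to [tooth_params()] when `params` is missing.
#' @return object of class `tooth_model` with `attachment_reduction = 0`.
#' @examples
#' model <- build_tooth(tooth_params("single_rooted"))
#' model$attachment_reduction
#' @export
build_tooth <- function(params = NULL, ...) {
  if (is.null(params)) params <- tooth_params(...)
  if (!inherits(params, "tooth_params")) params <- do.call(tooth_params, params)
  validate_tooth_params(params)
  multi <- params$tooth_class == "multi_rooted"
  half_spread <- if (multi) params$inter_root_spread / 2 else 0
  centers <- if (multi) rbind(c(-half_spread, 0), c(half_spread, 0))
             else rbind(c(0, 0))
  structure(list(
    params = params,
    tooth_class = params$tooth_class,
    centers = centers,
    attachment_reduction = 0,
    root_axis = c(0, 0, 1),          # +z apical, origin at the CEJ centroid
    origin = c(0, 0, 0)
  ), class = "tooth_model")
}

#' @export
print.tooth_model <- function(x, ...) {
  cat(sprintf("<tooth_model> %s, attachment reduction %g mm\n",
              x$tooth_class, x$attachment_reduction))
  print(x$params)
  invisible(x)
}

# ---- radius profiles -------------------------------------------------------

# apex cap height (rounded apex) in mm
apex_cap_height <- function(p) max(1.0, 1.5 * p$root_apical_radius)

# Root radius (cementum outer surface) at depth z below the CEJ.
root_radius <- function(p, z) {
  La <- p$root_length
  cap <- apex_cap_height(p)
  zs <- La - cap
  r <- ifelse(z <= zs,
              p$root_cervical_radius +
                (p$root_apical_radius - p$root_cervical_radius) * pmax(0, z) / zs,
              p$root_apical_radius *
                sqrt(pmax(0.1, 1 - 0.9 * ((pmin(z, La) - zs) / cap)^2)))
  pmin(r, p$root_cervical_radius)
}

# Crown radius (enamel outer surface) at height -z above the CEJ (z < 0).
crown_radius <- function(p, z) {
  s <- pmin(1, pmax(0, -z / p$crown_height))
  p$root_cervical_radius * (1 + 0.12 * sin(pi * s))
}

# Local slope factor 1/cos(alpha) of the root wall, used so that radial
# offsets produce the requested thickness normal to the surface.
slope_factor <- function(p, z, clamp = 1.8) {
  dz <- 1e-4
  dr <- (root_radius(p, z + dz) - root_radius(p, z - dz)) / (2 * dz)
  pmin(sqrt(1 + dr^2), clamp)
}

# Named ring radii of the cross-section template at plane z (one root).
# Rings outward-in: pdlo, pdlm (PDL), cemo (root surface), cemi, d1 (dentin),
# pulp.  For crown planes (z < 0) the cemo ring is the enamel surface.
plane_radii <- function(p, z) {
  if (z < 0) {
    cemo <- crown_radius(p, z)
    cemi <- cemo - p$enamel_thickness
    pulp <- p$pulp_scale * cemi
    d1 <- (cemi + pulp) / 2
    c(pdlo = cemo + p$pdl_thickness, pdlm = cemo + p$pdl_thickness / 2,
      cemo = cemo, cemi = cemi, d1 = d1, pulp = pulp)
  } else {
    zz <- min(z, p$root_length)
    sf <- slope_factor(p, zz)
    cemo <- root_radius(p, zz)
    tc <- min(cementum_thickness(zz / p$root_length) * sf, 0.3 * cemo)
    cemi <- cemo - tc
    g <- p$pdl_thickness * sf
    pulp <- p$pulp_scale * cemi
    d1 <- (cemi + pulp) / 2
    c(pdlo = cemo + g, pdlm = cemo + g / 2,
      cemo = cemo, cemi = cemi, d1 = d1, pulp = pulp)
  }
}

#' Root axis frame of a model
#'
#' @param model a `tooth_model`.
#' @return list with unit `axis` (+z, apical) and `origin` (CEJ centroid).
#' @export
root_axis <- function(model) list(axis = model$root_axis, origin = model$origin)

#' Furcation roof point of a multi-rooted model
#'
#' @param model a `tooth_model`.
#' @return length-3 point on the inter-radicular septum, or `NULL` for
#'   single-rooted models.
#' @export
furcation_roof_point <- function(model) {
  if (model$tooth_class != "multi_rooted") return(NULL)
  c(0, 0, model$params$furcation_depth_below_CEJ)
}

#' Reduce periodontal attachment
#'
#' Removes the PDL and the supporting alveolar bone coronal to a plane
#' perpendicular to the root axis, `reduction` mm below the CEJ.  The tooth
#' tissues themselves are unchanged; the exposed root surface is bare
#' cementum.  Reduction past the furcation depth of a multi-rooted model
#' exposes the furcation.
#'
#' @param model a `tooth_model`.
#' @param reduction attachment loss in mm, `0 <= reduction <= root_length`.
#' @return the updated model.
#' @export
reduce_attachment <- function(model, reduction) {
  stopifnot(inherits(model, "tooth_model"))
  if (!is.numeric(reduction) || length(reduction) != 1 || reduction < 0)
    stop("reduction must be a non-negative scalar (mm)")
  if (reduction > model$params$root_length)
    stop("reduction (", reduction, " mm) exceeds root_length (",
         model$params$root_length, " mm)")
  model$attachment_reduction <- reduction
  model
}

# ---- tissue boundary surfaces ---------------------------------------------

#' Extract the boundary surface of one tissue
#'
#' Builds (or reuses) a volume mesh of the model and extracts the closed
#' boundary surface of all elements of the given tissue.
#'
#' @param model a `tooth_model`.
#' @param tissue tissue name (e.g. `"pdl"`, `"dentin"`).
#' @param size mesh characteristic size (mm) used for the extraction.
#' @param mesh optional pre-built `fe_mesh` of the model.
#' @return a watertight `tri_surface`.
#' @export
tissue_surface <- function(model, tissue, size = 1.0, mesh = NULL) {
  if (is.null(mesh)) mesh <- generate_mesh(model, size = size, order = 1L)
  rid <- match(tissue, mesh$region_names)
  if (is.na(rid)) stop("tissue '", tissue, "' not present; regions: ",
                       paste(mesh$region_names, collapse = ", "))
  keep <- which(mesh$region == rid)
  if (!length(keep)) stop("tissue '", tissue, "' has no elements in this mesh")
  tets <- mesh$elems[keep, 1:4, drop = FALSE]
  fa <- face_adjacency(tets, rep(1L, length(keep)))
  bnd <- is.na(fa$elem2)
  corners <- as.matrix(fa[bnd, c("a", "b", "c")])
  cn <- compact_nodes(mesh$nodes, corners)
  tri_surface(cn$nodes, cn$tets)
}

#' All tissue boundary surfaces of a model
#'
#' @inheritParams tissue_surface
#' @return named list of `tri_surface` objects.
#' @export
tissue_surfaces <- function(model, size = 1.0) {
  mesh <- generate_mesh(model, size = size, order = 1L)
  present <- mesh$region_names[sort(unique(mesh$region))]
  setNames(lapply(present, tissue_surface, model = model, mesh = mesh), present)
}

# ---- external surface import ----------------------------------------------

#' Assemble a model from user-supplied tissue surfaces
#'
#' Reads one watertight surface mesh (STL or PLY, mm units) per tissue and
#' assembles an imported model.  Surfaces are validated for watertightness,
#' plausibility of units (bounding box under 1 m) and pairwise overlap.
#' A missing PDL surface can be synthesized by offsetting the root
#' (dentin/cementum) surface with [create_pdl_layer()].
#'
#' Imported models support geometric queries and export; volume meshing is
#' available only for parametric models built with [build_tooth()].
#'
#' @param paths named character vector or list, tissue -> surface file.
#' @param generate_pdl synthesize the PDL shell from the root surface when
#'   no `pdl` entry is given.
#' @param pdl_thickness thickness for the synthesized PDL (mm).
#' @return object of class `imported_tooth_model`.
#' @export
import_surfaces <- function(paths, generate_pdl = FALSE, pdl_thickness = 0.1) {
  paths <- as.list(paths)
  if (is.null(names(paths)) || any(!nzchar(names(paths))))
    stop("'paths' must be named by tissue")
  surfaces <- lapply(paths, read_surface)
  for (tissue in names(surfaces)) {
    s <- surfaces[[tissue]]
    if (!is_watertight(s))
      stop("surface for '", tissue, "' is not watertight: ", paths[[tissue]])
    ext <- apply(s$vertices, 2, function(v) diff(range(v)))
    if (any(ext > 1000))
      stop("surface for '", tissue, "' spans ", round(max(ext)),
           " mm; units look suspicious (expected mm)")
  }
  tn <- names(surfaces)
  if (length(tn) > 1) {
    for (i in seq_len(length(tn) - 1)) for (j in seq(i + 1, length(tn))) {
      si <- surfaces[[tn[i]]]; sj <- surfaces[[tn[j]]]
      probe_i <- si$vertices[round(seq(1, nrow(si$vertices), length.out =
                                         min(25, nrow(si$vertices)))), , drop = FALSE]
      probe_j <- sj$vertices[round(seq(1, nrow(sj$vertices), length.out =
                                         min(25, nrow(sj$vertices)))), , drop = FALSE]
      ins_ij <- any(apply(probe_i, 1, point_in_surface, s = sj))
      ins_ji <- any(apply(probe_j, 1, point_in_surface, s = si))
      if (ins_ij && ins_ji)
        stop("tissue solids '", tn[i], "' and '", tn[j], "' overlap")
    }
  }
  if (!"pdl" %in% names(surfaces) && generate_pdl) {
    root_tissue <- intersect(c("cementum", "dentin"), names(surfaces))[1]
    if (is.na(root_tissue))
      stop("generate_pdl needs a 'cementum' or 'dentin' surface")
    shell <- create_pdl_layer(surfaces[[root_tissue]], thickness = pdl_thickness)
    surfaces$pdl <- shell$outer
  }
  structure(list(surfaces = surfaces, attachment_reduction = 0),
            class = c("imported_tooth_model"))
}

#' Export a model's tissue surfaces to files
#'
#' @param model a `tooth_model` or `imported_tooth_model`.
#' @param dir output directory.
#' @param format `"stl"` or `"ply"`.
#' @param size mesh size for surface extraction of parametric models.
#' @return named character vector of written paths.
#' @export
export_surfaces <- function(model, dir, format = "ply", size = 1.0) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  surfs <- if (inherits(model, "imported_tooth_model")) model$surfaces
           else tissue_surfaces(model, size = size)
  paths <- vapply(names(surfs), function(tissue) {
    path <- file.path(dir, paste0(tissue, ".", format))
    write_surface(surfs[[tissue]], path, format = format)
    path
  }, "")
  paths
}
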