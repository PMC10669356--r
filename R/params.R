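#' Parametric tooth description
#'
#' Dimensions for the synthetic single- or multi-rooted tooth, its
#' periodontal ligament (PDL) and the surrounding alveolar bone block.
#' All lengths are millimetres.  The defaults are generic adult-tooth
#' dimensions (canine/premolar-like single-rooted tooth, two-rooted
#' molar); every value can be overridden.
#'
#' @param tooth_class `"single_rooted"` or `"multi_rooted"`.
#' @param root_length root height from the cemento-enamel junction (CEJ)
#'   to the apex, along the root axis.
#' @param crown_height crown height above the CEJ.
#' @param root_cervical_radius root radius at the CEJ (per root for
#'   multi-rooted teeth).
#' @param root_apical_radius root radius at the apical shoulder, before the
#'   rounded apex cap.
#' @param furcation_depth_below_CEJ multi-rooted only: depth of the
#'   furcation roof below the CEJ (0 < depth < root_length).
#' @param inter_root_spread multi-rooted only: centre-to-centre distance of
#'   the two roots.
#' @param enamel_thickness enamel cap thickness on the crown.
#' @param pulp_scale pulp chamber radius as a fraction of the dentin
#'   envelope radius.
#' @param pdl_thickness PDL layer thickness (uniform; 0.1 mm).
#' @param cortical_shell_thickness cortical shell thickness at the outer
#'   faces of the bone block.
#' @param bone_block_dims numeric length-3, bone block width (x), depth (y)
#'   and height below the CEJ (z).
#' @param include_gingiva include a gingival collar over exposed root
#'   surfaces (mechanically negligible; off by default).
#' @return object of class `tooth_params`.
#' @export
tooth_params <- function(tooth_class = c("single_rooted", "multi_rooted"),
                         root_length = NULL,
                         crown_height = NULL,
                         root_cervical_radius = NULL,
                         root_apical_radius = NULL,
                         furcation_depth_below_CEJ = NULL,
                         inter_root_spread = NULL,
                         enamel_thickness = 0.8,
                         pulp_scale = 0.35,
                         pdl_thickness = 0.1,
                         cortical_shell_thickness = 1.5,
                         bone_block_dims = NULL,
                         include_gingiva = FALSE) {
  tooth_class <- match.arg(tooth_class)
  multi <- tooth_class == "multi_rooted"
  root_length <- root_length %||% if (multi) 12 else 13
  crown_height <- crown_height %||% if (multi) 7 else 8
  root_cervical_radius <- root_cervical_radius %||% if (multi) 1.8 else 3.0
  root_apical_radius <- root_apical_radius %||% if (multi) 0.9 else 1.2
  if (multi) {
    furcation_depth_below_CEJ <- furcation_depth_below_CEJ %||% 3
    inter_root_spread <- inter_root_spread %||% 7
  }
  # port half-side of the O-grid square around each root: cervical radius,
  # the PDL, and room for the bone transition band
  hs <- root_cervical_radius + 0.7
  if (is.null(bone_block_dims)) {
    half_w <- if (multi) inter_root_spread / 2 + hs + 2.5 else hs + 2.8
    half_d <- hs + 2.8
    bone_block_dims <- c(2 * half_w, 2 * half_d, root_length + 4)
  }

  p <- structure(list(
    tooth_class = tooth_class,
    root_length = root_length,
    crown_height = crown_height,
    root_cervical_radius = root_cervical_radius,
    root_apical_radius = root_apical_radius,
    furcation_depth_below_CEJ = if (multi) furcation_depth_below_CEJ else NA_real_,
    inter_root_spread = if (multi) inter_root_spread else NA_real_,
    enamel_thickness = enamel_thickness,
    pulp_scale = pulp_scale,
    pdl_thickness = pdl_thickness,
    cortical_shell_thickness = cortical_shell_thickness,
    bone_block_dims = bone_block_dims,
    include_gingiva = isTRUE(include_gingiva),
    port_half_side = hs
  ), class = "tooth_params")
  validate_tooth_params(p)
  p
}

`%||%` <- function(a, b) if (is.null(a)) b else a

validate_tooth_params <- function(p) {
  chk <- function(cond, msg) if (!cond) stop("invalid tooth parameters: ", msg)
  pos <- c("root_length", "crown_height", "root_cervical_radius",
           "root_apical_radius", "enamel_thickness", "pdl_thickness",
           "cortical_shell_thickness")
  for (f in pos)
    chk(is.numeric(p[[f]]) && p[[f]] > 0, paste0(f, " must be > 0"))
  chk(p$root_apical_radius < p$root_cervical_radius,
      "root_apical_radius must be smaller than root_cervical_radius")
  chk(p$pulp_scale > 0.05 && p$pulp_scale < 0.8,
      "pulp_scale must lie in (0.05, 0.8) so the pulp stays strictly inside the dentin")
  chk(p$enamel_thickness < 0.6 * p$root_cervical_radius,
      "enamel_thickness too large for the crown envelope")
  chk(length(p$bone_block_dims) == 3 && all(p$bone_block_dims > 0),
      "bone_block_dims must be three positive lengths")
  W <- p$bone_block_dims[1]; D <- p$bone_block_dims[2]; H <- p$bone_block_dims[3]
  chk(H > p$root_length + 1.5,
      "bone block height must exceed root_length by at least 1.5 mm of apical bone")
  t <- p$cortical_shell_thickness
  chk(t < min(W, D) / 4, "cortical shell thicker than the bone block allows")
  if (p$tooth_class == "multi_rooted") {
    chk(is.numeric(p$furcation_depth_below_CEJ) &&
          p$furcation_depth_below_CEJ > 0 &&
          p$furcation_depth_below_CEJ < p$root_length,
        "furcation_depth_below_CEJ must lie strictly between 0 and root_length")
    c2 <- p$inter_root_spread / 2
    chk(c2 > p$port_half_side + 0.4,
        "inter_root_spread too small: root envelopes (incl. PDL and bone transition) would overlap")
    chk(W / 2 > c2 + p$port_half_side + 1.0,
        "bone block width too small for the two roots plus lateral bone")
    chk(D / 2 > p$port_half_side + 1.0,
        "bone block depth too small for the root plus lateral bone")
  } else {
    chk(W / 2 > p$port_half_side + 1.0 && D / 2 > p$port_half_side + 1.0,
        "bone block too small for the root plus lateral bone")
  }
  invisible(p)
}

#' @export
print.tooth_params <- function(x, ...) {
  cat(sprintf("<tooth_params> %s\n", x$tooth_class))
  cat(sprintf("  root %g mm (cervical r %g, apical r %g), crown %g mm\n",
              x$root_length, x$root_cervical_radius, x$root_apical_radius,
              x$crown_height))
  if (x$tooth_class == "multi_rooted")
    cat(sprintf("  furcation %g mm below CEJ, root spread %g mm\n",
                x$furcation_depth_below_CEJ, x$inter_root_spread))
  cat(sprintf("  PDL %g mm, enamel %g mm, cortical shell %g mm, block %s mm\n",
              x$pdl_thickness, x$enamel_thickness, x$cortical_shell_thickness,
              paste(x$bone_block_dims, collapse = " x ")))
  invisible(x)
}
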