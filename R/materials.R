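#' @title Tissue material library
#'
#' @description Isotropic linear-elastic constants for the dental and
#' periodontal tissues used in the simulations.  Moduli are in MPa so that
#' the mm--N--MPa unit system is consistent (1 N/mm^2 = 1 MPa).  The
#' built-in entries are immutable; additional materials can be registered
#' at run time with [register_material()].
#'
#' @details The ligament, pulp and gingiva are soft, nearly incompressible
#' tissues (Poisson ratio 0.45); enamel, dentin and bone are stiff mineral
#' phases.  Cortical and cancellous bone differ by a factor of ten in
#' stiffness.
#' @name materials
NULL

.builtin_materials <- list(
  enamel          = list(name = "enamel",          elastic_modulus = 84000, poisson_ratio = 0.33),
  dentin          = list(name = "dentin",          elastic_modulus = 18600, poisson_ratio = 0.31),
  pulp            = list(name = "pulp",            elastic_modulus = 2.07,  poisson_ratio = 0.45),
  pdl             = list(name = "pdl",             elastic_modulus = 68.9,  poisson_ratio = 0.45),
  gingiva         = list(name = "gingiva",         elastic_modulus = 3.0,   poisson_ratio = 0.45),
  cortical_bone   = list(name = "cortical_bone",   elastic_modulus = 13700, poisson_ratio = 0.30),
  cancellous_bone = list(name = "cancellous_bone", elastic_modulus = 1370,  poisson_ratio = 0.30)
)

.material_env <- new.env(parent = emptyenv())

.all_materials <- function() {
  user <- as.list(.material_env)
  c(.builtin_materials, user[setdiff(names(user), names(.builtin_materials))])
}

#' Construct a material specification
#'
#' @param name tissue label.
#' @param elastic_modulus Young's modulus in MPa (> 0).
#' @param poisson_ratio Poisson ratio in `[0, 0.5)`.
#' @return An object of class `material_spec`.
#' @export
material_spec <- function(name, elastic_modulus, poisson_ratio) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.numeric(elastic_modulus) || elastic_modulus <= 0)
    stop("elastic_modulus must be > 0 (got ", elastic_modulus, ")")
  if (!is.numeric(poisson_ratio) || poisson_ratio < 0 || poisson_ratio >= 0.5)
    stop("poisson_ratio must lie in [0, 0.5) (got ", poisson_ratio, ")")
  structure(list(name = name,
                 elastic_modulus = as.numeric(elastic_modulus),
                 poisson_ratio = as.numeric(poisson_ratio)),
            class = "material_spec")
}

#' Look up a tissue material
#'
#' @param tissue tissue label, e.g. `"pdl"` or `"cortical_bone"`.
#' @return A `material_spec`.
#' @examples
#' get_material("pdl")          # 68.9 MPa, nu = 0.45
#' get_material("enamel")       # 84000 MPa, nu = 0.33
#' @export
get_material <- function(tissue) {
  lib <- .all_materials()
  if (!tissue %in% names(lib))
    stop("unknown tissue '", tissue, "'; available: ",
         paste(sort(names(lib)), collapse = ", "))
  m <- lib[[tissue]]
  material_spec(m$name, m$elastic_modulus, m$poisson_ratio)
}

#' Register a user material
#'
#' Built-in tissue entries cannot be overridden.
#' @inheritParams material_spec
#' @return The registered `material_spec`, invisibly.
#' @export
register_material <- function(name, elastic_modulus, poisson_ratio) {
  if (name %in% names(.builtin_materials))
    stop("built-in material '", name, "' is immutable")
  spec <- material_spec(name, elastic_modulus, poisson_ratio)
  assign(name, unclass(spec), envir = .material_env)
  invisible(spec)
}

#' Active material table
#'
#' @param path optional CSV path; when given the table is also written there.
#' @return data.frame with columns `name`, `elastic_modulus_MPa`,
#'   `poisson_ratio`.
#' @export
material_table <- function(path = NULL) {
  lib <- .all_materials()
  df <- data.frame(
    name = vapply(lib, `[[`, "", "name"),
    elastic_modulus_MPa = vapply(lib, `[[`, 0, "elastic_modulus"),
    poisson_ratio = vapply(lib, `[[`, 0, "poisson_ratio"),
    row.names = NULL
  )
  if (!is.null(path)) write.csv(df, path, row.names = FALSE)
  df
}

#' Lame parameters from engineering constants
#'
#' lambda = E nu / ((1 + nu)(1 - 2 nu)), mu = E / (2 (1 + nu)).
#' @param E Young's modulus (MPa).
#' @param nu Poisson ratio.
#' @return list with `lambda` and `mu` (MPa).
#' @export
lame_parameters <- function(E, nu) {
  if (nu >= 0.5) stop("incompressible limit (nu >= 0.5) unsupported")
  list(lambda = E * nu / ((1 + nu) * (1 - 2 * nu)),
       mu = E / (2 * (1 + nu)))
}

#' Engineering constants from Lame parameters
#'
#' Inverse of [lame_parameters()].
#' @param lambda,mu Lame constants (MPa).
#' @return list with `E` and `nu`.
#' @export
elastic_constants <- function(lambda, mu) {
  list(E = mu * (3 * lambda + 2 * mu) / (lambda + mu),
       nu = lambda / (2 * (lambda + mu)))
}

#' Isotropic stiffness matrix in Voigt form
#'
#' Voigt order `(xx, yy, zz, xy, yz, xz)` with engineering shear strains, so
#' the three shear diagonal entries equal the shear modulus mu.
#'
#' @param spec a `material_spec` (or any list with `elastic_modulus` and
#'   `poisson_ratio`).
#' @return symmetric positive-definite 6x6 matrix (MPa).
#' @export
isotropic_elastic_tensor <- function(spec) {
  lm <- lame_parameters(spec$elastic_modulus, spec$poisson_ratio)
  D <- matrix(0, 6, 6)
  D[1:3, 1:3] <- lm$lambda
  diag(D)[1:3] <- lm$lambda + 2 * lm$mu
  diag(D)[4:6] <- lm$mu
  D
}

#' Default tissue -> material mapping for a mesh
#'
#' Cementum is not tabulated separately in the tissue library; by default it
#' inherits the dentin constants (the two mineralized root tissues are
#' elastically close, and the 50-150 um layer is mechanically dominated by
#' its neighbours).  Override via `overrides$cementum` to study it.
#'
#' @param regions character vector of region (tissue) names.
#' @param overrides optional named list of `material_spec`s taking precedence
#'   over the library.
#' @return named list of `material_spec`, one per region.
#' @export
materials_for <- function(regions, overrides = NULL) {
  out <- lapply(regions, function(r) {
    if (!is.null(overrides) && r %in% names(overrides)) {
      m <- overrides[[r]]
      material_spec(r, m$elastic_modulus, m$poisson_ratio)
    } else if (r == "cementum") {
      d <- get_material("dentin")
      material_spec("cementum", d$elastic_modulus, d$poisson_ratio)
    } else get_material(r)
  })
  names(out) <- regions
  out
}

#' @export
print.material_spec <- function(x, ...) {
  cat(sprintf("<material> %s: E = %g MPa, nu = %g\n",
              x$name, x$elastic_modulus, x$poisson_ratio))
  invisible(x)
}
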