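#' Occlusal load protocol
#'
#' A linear force ramp applied as uniform traction over a facet set
#' (the occlusal contact patch by default).  The force at step k of n is
#' `(k/n)` times the terminal force.  The axial component acts along the
#' root axis (+z, pressing the tooth into its socket); the transverse
#' (ventral) component acts along +x.  The whole-jaw masseter protocol is
#' a 70-step ramp to 700 N axial and 350 N transverse; a single-tooth
#' submodel uses a tenth of that by default, and [calibrate_load()] can
#' rescale the protocol against a pressure anchor.
#'
#' @param n_steps number of ramp steps (>= 1).
#' @param axial_N terminal axial force (N).
#' @param transverse_N terminal transverse (ventral) force (N).
#' @param application facet-set name carrying the traction.
#' @return object of class `load_protocol`.
#' @examples
#' resultant_force(load_protocol(axial_N = 700, transverse_N = 350)) # 782.6 N
#' @export
load_protocol <- function(n_steps = 70L, axial_N = 70, transverse_N = 35,
                          application = "occlusal_patch") {
  if (!is.numeric(n_steps) || n_steps < 1) stop("n_steps must be >= 1")
  structure(list(n_steps = as.integer(n_steps),
                 axial_N = axial_N, transverse_N = transverse_N,
                 application = application),
            class = "load_protocol")
}

#' @export
print.load_protocol <- function(x, ...) {
  cat(sprintf("<load_protocol> %d steps to (axial %g N, transverse %g N), resultant %.1f N on '%s'\n",
              x$n_steps, x$axial_N, x$transverse_N, resultant_force(x),
              x$application))
  invisible(x)
}

#' Resultant terminal force of a protocol
#'
#' Euclidean norm of the terminal force components.
#' @param protocol a [load_protocol()] (or numeric length-2 `(axial,
#'   transverse)`).
#' @return resultant force in N.
#' @export
resultant_force <- function(protocol) {
  f <- if (inherits(protocol, "load_protocol"))
    c(protocol$axial_N, protocol$transverse_N) else as.numeric(protocol)
  sqrt(sum(f^2))
}

scale_protocol <- function(protocol, factor) {
  protocol$axial_N <- protocol$axial_N * factor
  protocol$transverse_N <- protocol$transverse_N * factor
  protocol
}

terminal_force_vector <- function(protocol) {
  c(protocol$transverse_N, 0, protocol$axial_N)
}

#' Assemble the linear-elastic system for a mesh
#'
#' Standard displacement-based finite-element assembly: 4-point quadrature
#' on 10-node tetrahedra (exact for their quadratic stiffness integrand),
#' single-point on 4-node tetrahedra.  The unconstrained stiffness is
#' symmetric positive-semidefinite with the six rigid-body modes in its
#' null space.
#'
#' @param mesh an `fe_mesh`.
#' @param materials named list of material specs per region; defaults to the
#'   tissue library entries matching the mesh region names.
#' @return object of class `fe_system` (stiffness, mesh, materials).
#' @export
assemble <- function(mesh, materials = NULL) {
  if (isTRUE(mesh$unsupported))
    stop("model is unsupported (PDL reduced below one element row); refusing to assemble")
  materials <- materials %||% materials_for(mesh$region_names)
  missing <- setdiff(mesh$region_names, names(materials))
  if (length(missing))
    stop("no material for region(s): ", paste(missing, collapse = ", "))
  Evec <- vapply(materials[mesh$region_names], `[[`, 0, "elastic_modulus")[mesh$region]
  nuvec <- vapply(materials[mesh$region_names], `[[`, 0, "poisson_ratio")[mesh$region]
  tr <- fem_assemble_triplets(mesh$nodes, mesh$elems, Evec, nuvec)
  ndof <- 3L * nrow(mesh$nodes)
  K <- Matrix::sparseMatrix(i = tr$i, j = tr$j, x = tr$x,
                            dims = c(ndof, ndof), symmetric = TRUE)
  rm(tr)
  structure(list(K = K, mesh = mesh, materials = materials,
                 E = Evec, nu = nuvec, ndof = ndof,
                 fixed = rep(FALSE, ndof)),
            class = "fe_system")
}

#' Apply displacement supports
#'
#' @param system an `fe_system`.
#' @param support facet-set name to constrain (default the outer bone
#'   boundary of the alveolar submodel), or `NULL` when `nodes` are given.
#' @param kind only `"fixed"` (all components zero) is offered for facet
#'   sets; component-wise constraints are available through `nodes` /
#'   `components` for verification problems.
#' @param nodes optional explicit node ids to constrain.
#' @param components displacement components (1 = x, 2 = y, 3 = z) to fix
#'   for `nodes`.
#' @return the updated `fe_system`.
#' @export
apply_supports <- function(system, support = "outer_bone_boundary",
                           kind = "fixed", nodes = NULL, components = 1:3) {
  stopifnot(inherits(system, "fe_system"))
  kind <- match.arg(kind, "fixed")
  if (is.null(nodes)) {
    fs <- system$mesh$facet_sets[[support]]
    if (is.null(fs) || nrow(fs$corners) == 0)
      stop("support facet set '", support, "' is empty: problem is ill-posed")
    nodes <- unique(c(as.vector(fs$corners), as.vector(fs$mid)))
    components <- 1:3
  }
  nodes <- unique(as.integer(nodes))
  if (length(nodes) == 0) stop("no support nodes: problem is ill-posed")
  if (length(nodes) == 1 && length(components) < 3)
    warning("point constraint on a single node")
  dofs <- as.vector(outer(components - 1L, 3L * (nodes - 1L), `+`)) + 1L
  system$fixed[dofs] <- TRUE
  system
}

#' Consistent nodal forces for a uniform total force on a facet set
#'
#' The total force is distributed as a uniform traction over the facet set
#' area; quadratic facets receive the consistent midside loading.
#'
#' @param mesh an `fe_mesh`.
#' @param facet_set facet-set name.
#' @param force total force vector (N), length 3.
#' @return load vector of length `3 * n_nodes`.
#' @export
traction_load <- function(mesh, facet_set, force) {
  fs <- mesh$facet_sets[[facet_set]]
  if (is.null(fs) || nrow(fs$corners) == 0)
    stop("facet set '", facet_set, "' is empty")
  g <- facet_geometry(mesh, facet_set)
  A <- sum(g$area)
  traction <- force / A
  f <- numeric(3L * nrow(mesh$nodes))
  addf <- function(node_ids, weights) {
    for (d in 1:3) {
      v <- rowsum(weights * traction[d], group = node_ids)
      rows <- as.integer(rownames(v))
      f[3 * (rows - 1) + d] <<- f[3 * (rows - 1) + d] + v[, 1]
    }
  }
  if (mesh$order == 2L) {
    # straight-sided quadratic triangle: corner weights 0, midside A/3
    for (k in 1:3) addf(fs$mid[, k], g$area / 3)
  } else {
    for (k in 1:3) addf(fs$corners[, k], g$area / 3)
  }
  f
}

#' Solve the constrained static system
#'
#' Direct sparse Cholesky factorization of the constrained stiffness.
#'
#' @param system an `fe_system` with supports applied.
#' @param f load vector (length `3 n`).
#' @return list with nodal displacements `u` (length `3 n`), `reactions`
#'   at constrained dofs, and relative residual `residual`.
#' @export
solve_system <- function(system, f) {
  if (!any(system$fixed)) stop("no supports applied; stiffness is singular")
  free <- which(!system$fixed)
  Kff <- system$K[free, free]
  ch <- Matrix::Cholesky(Matrix::forceSymmetric(Kff), LDL = FALSE, super = TRUE)
  uf <- as.numeric(Matrix::solve(ch, f[free]))
  u <- numeric(system$ndof)
  u[free] <- uf
  r <- as.numeric(system$K %*% u) - f
  reactions <- r
  reactions[free] <- 0
  fn <- sqrt(sum(f[free]^2))
  residual <- if (fn > 0) sqrt(sum((r[free])^2)) / fn else 0
  # linearity: an independent solve at half load must equal half the field
  lin <- 0
  un <- sqrt(sum(uf^2))
  if (un > 0) {
    u_half <- as.numeric(Matrix::solve(ch, 0.5 * f[free]))
    lin <- sqrt(sum((u_half - 0.5 * uf)^2)) / (0.5 * un)
  }
  list(u = u, reactions = reactions, residual = residual, linearity = lin)
}

new_solution_field <- function(mesh, u, stress, load_fraction, applied_force,
                               checks) {
  structure(list(u = u, stress = stress, load_fraction = load_fraction,
                 applied_force = applied_force, checks = checks, mesh = mesh),
            class = "solution_field")
}

#' @export
print.solution_field <- function(x, ...) {
  cat(sprintf("<solution_field> load fraction %.3f, applied force (%.3g, %.3g, %.3g) N\n",
              x$load_fraction, x$applied_force[1], x$applied_force[2],
              x$applied_force[3]))
  cat(sprintf("  max |u| = %.4g mm; equilibrium %.2e, linearity %.2e\n",
              x$checks$max_disp, x$checks$equilibrium_rel, x$checks$linearity_rel))
  invisible(x)
}

#' Run the ramped load protocol
#'
#' The model is linear, so each ramp step is an exact scaling of one
#' factorized terminal solve; equilibrium (reaction sum against applied
#' load) and load-scaling linearity are verified numerically on every run
#' rather than assumed.
#'
#' @param system a supported `fe_system`.
#' @param protocol a [load_protocol()].
#' @param keep `"terminal"` (default) returns only the terminal-step field,
#'   `"all"` one `solution_field` per ramp step.
#' @return a `solution_field`, or a list of them when `keep = "all"`.
#' @export
run_load_protocol <- function(system, protocol = load_protocol(),
                              keep = c("terminal", "all")) {
  keep <- match.arg(keep)
  mesh <- system$mesh
  force <- terminal_force_vector(protocol)
  f <- traction_load(mesh, protocol$application, force)
  sol <- solve_system(system, f)
  stress <- fem_element_stress(mesh$nodes, mesh$elems, sol$u,
                               system$E, system$nu)
  # equilibrium: reactions balance the applied load
  R <- colSums(matrix(sol$reactions, ncol = 3, byrow = TRUE))
  eq_rel <- sqrt(sum((R + force)^2)) / sqrt(sum(force^2))
  # linearity: the independently solved half-load field equals half the
  # terminal field (computed in solve_system with the factorization in hand)
  lin_rel <- sol$linearity
  checks <- list(equilibrium_rel = eq_rel, linearity_rel = lin_rel,
                 solver_residual = sol$residual, max_disp = max(abs(sol$u)))
  terminal <- new_solution_field(mesh, sol$u, stress, 1.0, force, checks)
  if (keep == "terminal") return(terminal)
  lapply(seq_len(protocol$n_steps), function(k) {
    frac <- k / protocol$n_steps
    new_solution_field(mesh, frac * sol$u, frac * stress, frac, frac * force,
                       checks)
  })
}

#' One-call static solve of a tooth model
#'
#' Convenience wrapper: mesh, assemble, support the outer bone boundary,
#' run the load protocol, return the terminal solution (with its mesh).
#'
#' @param model a `tooth_model`.
#' @param protocol a [load_protocol()].
#' @param size,order meshing controls, see [generate_mesh()].
#' @param mesh optional pre-built mesh (overrides `size`/`order`).
#' @param materials optional material overrides.
#' @return terminal `solution_field` (mesh accessible as `$mesh`).
#' @export
solve_static <- function(model, protocol = load_protocol(), size = 1.2,
                         order = 2L, mesh = NULL, materials = NULL) {
  mesh <- mesh %||% generate_mesh(model, size = size, order = order)
  system <- assemble(mesh, materials)
  system <- apply_supports(system, "outer_bone_boundary")
  run_load_protocol(system, protocol, keep = "terminal")
}
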