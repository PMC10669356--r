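# Finite-element core verification: hand-assembled stiffness, rigid-body
# modes, patch tests, load protocol and equilibrium/linearity checks.

# independent R-side oracle for a single linear tetrahedron stiffness
tet4_stiffness_oracle <- function(X, E, nu) {
  ones <- cbind(1, X)
  V <- det(ones) / 6
  C <- solve(ones)              # rows: coefficients; grad L_k = C[2:4, k]
  B <- matrix(0, 6, 12)
  for (k in 1:4) {
    g <- C[2:4, k]
    B[1, 3 * k - 2] <- g[1]; B[2, 3 * k - 1] <- g[2]; B[3, 3 * k] <- g[3]
    B[4, 3 * k - 2] <- g[2]; B[4, 3 * k - 1] <- g[1]
    B[5, 3 * k - 1] <- g[3]; B[5, 3 * k] <- g[2]
    B[6, 3 * k - 2] <- g[3]; B[6, 3 * k] <- g[1]
  }
  D <- isotropic_elastic_tensor(list(elastic_modulus = E, poisson_ratio = nu))
  V * t(B) %*% D %*% B
}

one_tet_mesh <- function(X) {
  structure(list(nodes = X, elems = matrix(1:4, 1), region = 1L,
                 region_names = "block", order = 1L, facet_sets = list(),
                 unsupported = FALSE),
            class = "fe_mesh")
}

test_that("assembled single-tet stiffness matches hand assembly", {
  set.seed(3)
  X <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)) +
    matrix(runif(12, -0.1, 0.1), 4)
  for (pars in list(c(1, 0), c(18600, 0.31), c(68.9, 0.45))) {
    sys <- assemble(one_tet_mesh(X),
                    materials = list(block = material_spec("block", pars[1],
                                                           pars[2])))
    K <- as.matrix(sys$K)
    expect_equal(K, unname(tet4_stiffness_oracle(X, pars[1], pars[2])),
                 tolerance = 1e-12)
    expect_equal(K, t(K))
  }
})

test_that("the unconstrained stiffness has exactly six rigid-body modes", {
  m <- block_mesh(c(1, 1, 1), c(2, 2, 2), order = 1L)
  sys <- assemble(m, materials = list(block = get_material("dentin")))
  ev <- eigen(as.matrix(sys$K), symmetric = TRUE, only.values = TRUE)$values
  scale <- max(ev)
  expect_identical(sum(abs(ev) / scale < 1e-10), 6L)
  expect_gt(ev[length(ev) - 6] / scale, 1e-8)
})

test_that("quadratic elements pass the uniaxial patch test for all tissues", {
  for (tissue in c("enamel", "dentin", "pulp", "pdl", "gingiva",
                   "cortical_bone", "cancellous_bone")) {
    ps <- patch_solve(get_material(tissue), n = c(2, 2, 2), order = 2L)
    expect_lt(max(abs(ps$stress[, 3] - 1)), 1e-8)
    expect_lt(max(abs(ps$stress[, -3])), 1e-8)
    E <- unname(ps$sys$E[1]); nu <- unname(ps$sys$nu[1])
    top <- which(abs(ps$mesh$nodes[, 3] - 1) < 1e-12)
    expect_equal(mean(ps$sol$u[3 * (top - 1) + 3]), 1 / E, tolerance = 1e-8)
  }
})

test_that("fully fixed block under zero load stays at rest", {
  m <- block_mesh(c(1, 1, 1), c(2, 2, 2), order = 1L)
  sys <- assemble(m, materials = list(block = get_material("dentin")))
  for (s in c("xmin", "xmax", "ymin", "ymax", "zmin", "zmax"))
    sys <- apply_supports(sys, support = s)
  sol <- solve_system(sys, numeric(sys$ndof))
  expect_equal(max(abs(sol$u)), 0)
})

test_that("support handling catches ill-posed and point constraints", {
  m <- coarse_single_mesh()
  sys <- assemble(m)
  expect_error(apply_supports(sys, support = "no_such_set"), "empty")
  expect_warning(apply_supports(sys, nodes = 1L, components = 3L), "point")
  sys2 <- assemble(m)
  expect_error(solve_system(sys2, numeric(sys2$ndof)), "singular|support")
})

test_that("the load protocol resultant follows the Euclidean norm", {
  expect_equal(round(resultant_force(load_protocol(axial_N = 700,
                                                   transverse_N = 350)), 1),
               782.6)
  expect_equal(resultant_force(c(3, 4)), 5)
  expect_equal(resultant_force(c(0, 0)), 0)
})

test_that("ramp steps are exact scalings of the terminal solve", {
  m <- generate_mesh(single_model(), size = 2.6, order = 1L)
  sys <- assemble(m)
  sys <- apply_supports(sys, "outer_bone_boundary")
  all_steps <- run_load_protocol(sys, load_protocol(n_steps = 5), keep = "all")
  one <- run_load_protocol(sys, load_protocol(n_steps = 1), keep = "terminal")
  expect_length(all_steps, 5)
  expect_equal(all_steps[[5]]$u, one$u, tolerance = 1e-12)
  expect_equal(all_steps[[2]]$u, 0.4 * one$u, tolerance = 1e-12)
  expect_equal(all_steps[[2]]$load_fraction, 0.4)
})

test_that("every solve satisfies equilibrium and load-scaling linearity", {
  m <- generate_mesh(single_model(), size = 2.6, order = 1L)
  sys <- assemble(m)
  sys <- apply_supports(sys, "outer_bone_boundary")
  sol <- run_load_protocol(sys, load_protocol(), keep = "terminal")
  expect_lt(sol$checks$equilibrium_rel, 1e-6)
  expect_lt(sol$checks$linearity_rel, 1e-9)
})

test_that("traction loads integrate to the requested total force", {
  m <- block_mesh(c(2, 3, 1), c(3, 3, 2), order = 2L)
  f <- traction_load(m, "zmax", c(1.5, -2, 4))
  F <- colSums(matrix(f, ncol = 3, byrow = TRUE))
  expect_equal(F, c(1.5, -2, 4), tolerance = 1e-12)
})

test_that("the solver refuses a model with no remaining ligament support", {
  model <- reduce_attachment(single_model(), 13)
  m <- generate_mesh(model, size = 2.6, order = 1L)
  expect_true(m$unsupported)
  expect_error(assemble(m), "unsupported")
})
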