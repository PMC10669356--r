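# Contact-pressure extraction, stress invariants, zone summaries, failure
# detection and field export.

# two tagged regions of identical material, so the uniaxial field stays
# exactly uniform and the interface traction has a closed form
bimaterial_column <- function(order = 2L, split = "z") {
  rf <- switch(split,
               z = function(x, y, z) ifelse(z < 1, "lower", "upper"),
               x = function(x, y, z) ifelse(x < 0.5, "lower", "upper"))
  block_mesh(c(1, 1, 2), c(2, 2, 4), order = order, region_fun = rf)
}

compress_column <- function(m, force = c(0, 0, -1)) {
  d <- get_material("dentin")
  sys <- assemble(m, materials = list(lower = d, upper = d))
  base <- which(abs(m$nodes[, 3]) < 1e-12)
  sys <- apply_supports(sys, nodes = base, components = 3)
  o <- which(rowSums(abs(m$nodes)) < 1e-12)
  sys <- suppressWarnings(apply_supports(sys, nodes = o, components = 1:2))
  o2 <- which(abs(m$nodes[, 1]) < 1e-12 & abs(m$nodes[, 2] - 1) < 1e-12 &
                abs(m$nodes[, 3]) < 1e-12)
  sys <- suppressWarnings(apply_supports(sys, nodes = o2, components = 1))
  f <- traction_load(m, "zmax", force)
  sol <- solve_system(sys, f)
  stress <- periofem:::fem_element_stress(m$nodes, m$elems, sol$u, sys$E,
                                          sys$nu)
  periofem:::new_solution_field(m, sol$u, stress, 1, force,
                                list(equilibrium_rel = 0, linearity_rel = 0,
                                     max_disp = max(abs(sol$u))))
}

test_that("uniaxial compression across the interface reads +1 MPa everywhere", {
  m <- bimaterial_column(split = "z")
  sol <- compress_column(m)            # 1 N over 1 mm^2, compressive
  pm <- contact_pressure(sol, m, interface = "interface")
  expect_lt(max(abs(pm$facets$pressure - 1)), 1e-8)
  expect_equal(pm$peak, 1, tolerance = 1e-8)
  expect_equal(pm$mean, 1, tolerance = 1e-8)
})

test_that("an interface parallel to the load carries no normal traction", {
  m <- bimaterial_column(split = "x")
  sol <- compress_column(m)
  pm <- contact_pressure(sol, m, interface = "interface")
  expect_lt(max(abs(pm$facets$pressure)), 1e-8)
})

test_that("zero load produces zero pressure and flipping the load flips signs", {
  m <- bimaterial_column(split = "z")
  sol0 <- compress_column(m, force = c(0, 0, 0))
  pm0 <- contact_pressure(sol0, m, interface = "interface")
  expect_equal(max(abs(pm0$facets$pressure)), 0)
  sol_t <- compress_column(m, force = c(0, 0, 1))   # tension
  pm_t <- contact_pressure(sol_t, m, interface = "interface")
  sol_c <- compress_column(m, force = c(0, 0, -1))
  pm_c <- contact_pressure(sol_c, m, interface = "interface")
  expect_equal(pm_t$facets$pressure, -pm_c$facets$pressure, tolerance = 1e-12)
})

test_that("stress invariants match brute-force eigensolutions", {
  hydro <- stress_invariants(matrix(c(2, 2, 2, 0, 0, 0), 1))
  expect_equal(hydro$von_mises, 0)
  expect_equal(c(hydro$s1, hydro$s2, hydro$s3), c(2, 2, 2))
  uni <- stress_invariants(matrix(c(3, 0, 0, 0, 0, 0), 1))
  expect_equal(uni$von_mises, 3)
  set.seed(11)
  for (k in 1:20) {
    v <- rnorm(6)
    S <- matrix(c(v[1], v[4], v[6],
                  v[4], v[2], v[5],
                  v[6], v[5], v[3]), 3)
    ref <- sort(eigen(S, symmetric = TRUE, only.values = TRUE)$values,
                decreasing = TRUE)
    got <- stress_invariants(matrix(v, 1))
    expect_equal(c(got$s1, got$s2, got$s3), ref, tolerance = 1e-10)
  }
})

test_that("zones partition the interface and a uniform map has equal means", {
  m <- coarse_multi_mesh()
  g <- facet_geometry(m, "pdl_bone_interface")
  fake <- structure(list(facets = data.frame(
    x = g$centroid[, 1], y = g$centroid[, 2], z = g$centroid[, 3],
    area = g$area, tx = 0, ty = 0, tz = g$area * 0 + 1,
    pressure = rep(0.5, length(g$area)))),
    class = "contact_pressure_map")
  rs <- regional_summary(fake, multi_model())
  expect_equal(sum(rs$area_mm2), sum(g$area), tolerance = 1e-6)
  means <- rs$mean_MPa[rs$area_mm2 > 0]
  expect_true(all(abs(means - 0.5) < 1e-12))
  expect_gt(rs$area_mm2[rs$zone == "furcation_roof"], 0)
  # single-rooted models have an empty furcation zone
  m1 <- coarse_single_mesh()
  g1 <- facet_geometry(m1, "pdl_bone_interface")
  fake1 <- structure(list(facets = data.frame(
    x = g1$centroid[, 1], y = g1$centroid[, 2], z = g1$centroid[, 3],
    area = g1$area, tx = 0, ty = 0, tz = 1, pressure = 1)),
    class = "contact_pressure_map")
  rs1 <- regional_summary(fake1, single_model())
  expect_identical(rs1$area_mm2[rs1$zone == "furcation_roof"], 0)
})

test_that("failure detection follows the threshold-crossing rules", {
  v <- detect_failure(c(0.4, 0.5, 0.95), threshold_MPa = 0.9)
  expect_true(v$failed)
  expect_identical(v$criterion, "pressure_threshold")
  expect_equal(v$triggering_reduction, 2)   # third entry of the 0,1,2 grid
  v2 <- detect_failure(c(0.4, 0.5, 0.6), threshold_MPa = 0.9)
  expect_false(v2$failed)
  h <- data.frame(reduction = c(0, 1, 2), peak_MPa = c(0.4, NA, NA),
                  solver_ok = c(TRUE, FALSE, FALSE))
  v3 <- detect_failure(h)
  expect_true(v3$failed)
  expect_identical(v3$criterion, "solver_failure")
  expect_equal(v3$triggering_reduction, 1)
  # exactly at the threshold is not yet failure
  v4 <- detect_failure(c(0.5, 0.9), threshold_MPa = 0.9)
  expect_false(v4$failed)
})

test_that("field export writes VTU/CSV/PNG and the VTU round-trips", {
  m <- bimaterial_column(split = "z")
  sol <- compress_column(m)
  pm <- contact_pressure(sol, m, interface = "interface")
  dir <- tempfile()
  out <- export_fields(sol, m, pressure = pm, dir = dir, prefix = "t")
  expect_true(all(file.exists(out)))
  r <- read_vtu(out["vtu"])
  expect_equal(r$point_data$displacement,
               matrix(sol$u, ncol = 3, byrow = TRUE), tolerance = 1e-12)
  csv <- read.csv(out["pressure_csv"])
  expect_identical(nrow(csv), nrow(pm$facets))
  expect_error(export_fields(sol, m, dir = file.path("/proc/none", "x")),
               "cannot")
})
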