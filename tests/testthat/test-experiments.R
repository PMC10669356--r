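# Sweep orchestration on deliberately coarse meshes (order 1) so the suite
# stays fast; the physics-level assertions run in the acceptance tests.

coarse_sweep <- function(reductions = c(0, 2), threshold = 1e6) {
  fixture(paste0("sweep_", paste(reductions, collapse = "_"), "_", threshold),
          function()
            run_sweep(tooth_params("single_rooted"), reductions = reductions,
                      size = 2.6, order = 1L,
                      failure_threshold_MPa = threshold))
}

test_that("a single-point sweep equals the baseline solve", {
  sw <- run_sweep(tooth_params("single_rooted"), reductions = 0, size = 2.6,
                  order = 1L, failure_threshold_MPa = 100)
  model <- single_model()
  sol <- solve_static(model, size = 2.6, order = 1L)
  pm <- contact_pressure(sol)
  expect_equal(sw$rows$peak_MPa[1], pm$peak, tolerance = 1e-12)
  expect_false(sw$verdict$failed)
})

test_that("sweep input validation", {
  expect_error(run_sweep(tooth_params(), reductions = c(2, 1)), "increasing")
  expect_error(run_sweep(tooth_params(), reductions = c(0, 20)),
               "root_length")
})

test_that("calibration scales the protocol so the baseline peak hits the anchor", {
  model <- single_model()
  prot <- calibrate_load(model, anchor_MPa = 0.5, size = 2.6, order = 1L)
  expect_equal(prot$axial_N / prot$transverse_N, 2, tolerance = 1e-12)
  sol <- solve_static(model, protocol = prot, size = 2.6, order = 1L)
  expect_equal(contact_pressure(sol)$peak, 0.5, tolerance = 1e-9)
})

test_that("sweeps stop one confirmation step after the first failure", {
  sw <- run_sweep(tooth_params("single_rooted"), reductions = c(0, 1, 2, 3, 4),
                  size = 2.6, order = 1L, failure_threshold_MPa = 1e-6)
  expect_true(sw$verdict$failed)
  expect_identical(sum(sw$rows$evaluated), 2L)
  expect_false(any(sw$rows$evaluated[3:5]))
})

scale_protocol_for_test <- function(p, f) {
  p$axial_N <- p$axial_N * f
  p$transverse_N <- p$transverse_N * f
  p
}

test_that("class comparison is symmetric and checks calibration", {
  sw <- coarse_sweep()
  cmp <- compare_tooth_classes(sw, sw)
  expect_true(cmp$multi_ge_single)
  expect_equal(cmp$table$baseline_peak_MPa[1], cmp$table$baseline_peak_MPa[2])
  expect_identical(cmp$curves$single$normalized, cmp$curves$multi$normalized)
  other <- coarse_sweep()
  other$metadata$protocol <- scale_protocol_for_test(other$metadata$protocol, 2)
  expect_error(compare_tooth_classes(sw, other), "calibration")
})

test_that("plotted pressure data are exactly linear in force", {
  sw <- coarse_sweep()
  dir <- tempfile()
  files <- plot_pressure_surface(sw, dir = dir)
  expect_true(all(file.exists(files)))
  grid <- read.csv(files["csv"])
  for (red in unique(grid$reduction_mm)) {
    g <- grid[grid$reduction_mm == red, ]
    slope <- g$pressure_MPa[nrow(g)] / g$force_N[nrow(g)]
    expect_lt(max(abs(g$pressure_MPa - slope * g$force_N)),
              1e-9 * max(g$pressure_MPa))
  }
  one <- run_sweep(tooth_params("single_rooted"), reductions = 0, size = 2.6,
                   order = 1L)
  expect_error(plot_pressure_surface(one), "two")
})

test_that("sweeps are bitwise reproducible", {
  a <- run_sweep(tooth_params("single_rooted"), reductions = c(0, 2),
                 size = 2.6, order = 1L)
  b <- run_sweep(tooth_params("single_rooted"), reductions = c(0, 2),
                 size = 2.6, order = 1L)
  expect_identical(a$rows, b$rows)
})

test_that("yaml-config runs drive a sweep end to end", {
  cfg_path <- tempfile(fileext = ".yaml")
  writeLines(c(
    "tooth:",
    "  tooth_class: single_rooted",
    "reduction_mm: [0, 2]",
    "load: {n_steps: 10, axial_N: 70, transverse_N: 35}",
    "mesh: {size: 2.6, order: 1}",
    "failure_threshold_MPa: 100"), cfg_path)
  out <- tempfile()
  res <- run_from_config(cfg_path, out = out)
  expect_s3_class(res, "sweep_result")
  expect_true(file.exists(file.path(out, "results.csv")))
  expect_true(file.exists(file.path(out, "results.json")))
  tab <- read.csv(file.path(out, "results.csv"))
  expect_equal(tab$peak_MPa, res$rows$peak_MPa, tolerance = 1e-12)
  bad <- tempfile(fileext = ".yaml")
  writeLines("nonsense: 1", bad)
  expect_error(read_run_config(bad), "unknown config block")
})
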