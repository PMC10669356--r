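# Surface primitives, offset shells and the analytic shell-volume oracles.

test_that("primitive surfaces are watertight with correct volume and area", {
  cyl <- cylinder_surface(3, 10, n_theta = 96, n_z = 10)
  expect_true(is_watertight(cyl))
  # faceting shrinks the cross-section by the polygon/circle area ratio
  poly <- 96 / (2 * pi) * sin(2 * pi / 96)
  expect_equal(surface_volume(cyl), pi * 9 * 10 * poly, tolerance = 1e-9)
  hemi <- hemisphere_surface(5, n_theta = 96, n_phi = 48)
  expect_true(is_watertight(hemi))
  expect_equal(surface_volume(hemi), (2 / 3) * pi * 125, tolerance = 0.01)
  open <- tri_surface(cyl$vertices, cyl$faces[-1, ])
  expect_false(is_watertight(open))
})

test_that("ligament shell volume matches the annulus oracle on a cylinder", {
  cyl <- cylinder_surface(3, 10, n_theta = 128, n_z = 20)
  side <- function(v) sqrt(v[, 1]^2 + v[, 2]^2) > 3 - 1e-6
  shell <- create_pdl_layer(cyl, thickness = 0.1, region = side)
  expect_true(is_watertight(shell$outer))
  expect_equal(shell$volume, pi * (3.1^2 - 3^2) * 10, tolerance = 0.01)
})

test_that("ligament shell volume matches the spherical-shell oracle", {
  hemi <- hemisphere_surface(5, n_theta = 128, n_phi = 64)
  dome <- function(v) sqrt(rowSums(v^2)) > 5 - 1e-6
  shell <- create_pdl_layer(hemi, thickness = 0.1, region = dome)
  expect_equal(shell$volume, (2 / 3) * pi * (5.1^3 - 5^3), tolerance = 0.02)
})

test_that("degenerate shell inputs are rejected", {
  cyl <- cylinder_surface(2, 5, n_theta = 32, n_z = 5)
  expect_error(create_pdl_layer(cyl, thickness = 0), "positive")
  expect_error(create_pdl_layer(cyl, thickness = -0.1), "positive")
  open <- tri_surface(cyl$vertices, cyl$faces[-1, ])
  expect_error(create_pdl_layer(open, 0.1), "watertight")
})

test_that("self-intersecting offsets are detected with a location", {
  cyl <- cylinder_surface(1, 4, n_theta = 32, n_z = 8)
  expect_error(offset_surface(cyl, -1.5), "self-intersect")
})

test_that("cementum grading follows the three thickness steps", {
  expect_equal(cementum_thickness(c(0.1, 0.5, 0.9)), c(0.05, 0.10, 0.15))
  expect_equal(cementum_thickness(c(0, 1 / 3, 2 / 3, 1)),
               c(0.05, 0.10, 0.15, 0.15))
})

test_that("cementum shell volume matches the sum of three annuli", {
  cyl <- cylinder_surface(3, 12, n_theta = 96, n_z = 144)
  side <- function(v) sqrt(v[, 1]^2 + v[, 2]^2) > 3 - 1e-6
  cej <- cbind(3 * cos(seq(0, 2 * pi, length.out = 33))[-33],
               3 * sin(seq(0, 2 * pi, length.out = 33))[-33], 0)
  shell <- create_cementum_layer(cyl, cej, c(0, 0, 12), region = side)
  oracle <- 4 * pi * ((3^2 - 2.95^2) + (3^2 - 2.9^2) + (3^2 - 2.85^2))
  expect_equal(shell$volume, oracle, tolerance = 0.015)
})

test_that("a zero-height root (apex on the CEJ plane) is rejected", {
  cyl <- cylinder_surface(3, 12, n_theta = 32, n_z = 6)
  cej <- cbind(c(3, -3, 0, 0), c(0, 0, 3, -3), 0)
  expect_error(create_cementum_layer(cyl, cej, c(0, 0, 0)), "zero")
})

test_that("point-in-surface parity queries work on a cube", {
  cube <- cube_surface(1)
  expect_true(is_watertight(cube))
  expect_equal(surface_volume(cube), 1)
  expect_true(periofem:::point_in_surface(c(0.5, 0.5, 0.5), cube))
  expect_false(periofem:::point_in_surface(c(1.5, 0.5, 0.5), cube))
})
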