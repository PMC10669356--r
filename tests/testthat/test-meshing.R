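# Tetrahedral meshing: conformity, volume conservation, quality reporting,
# determinism and the convergence-study machinery.

test_that("a meshed unit cube conserves volume exactly", {
  m <- block_mesh(c(1, 1, 1), c(3, 3, 3), order = 1L)
  v <- periofem:::fem_tet_volumes(m$nodes, m$elems)
  expect_true(all(v > 0))
  expect_equal(sum(v), 1, tolerance = 1e-12)
})

test_that("prism splitting is conforming (every interior face is shared twice)", {
  m <- coarse_single_mesh()
  # face_adjacency() errors on any face used by more than two elements and
  # counts everything else; boundary + 2*interior must equal 4*elements
  fa <- periofem:::face_adjacency(m$elems[, 1:4], m$region)
  n_int <- sum(!is.na(fa$elem2))
  n_bnd <- sum(is.na(fa$elem2))
  expect_identical(n_bnd + 2L * n_int, 4L * nrow(m$elems))
})

test_that("no coincident duplicate nodes exist across interfaces", {
  m <- coarse_single_mesh()
  key <- paste(sprintf("%.9f", m$nodes[, 1]), sprintf("%.9f", m$nodes[, 2]),
               sprintf("%.9f", m$nodes[, 3]))
  expect_identical(anyDuplicated(key), 0L)
})

test_that("bimaterial interfaces are tagged with one element on each side", {
  m <- block_mesh(c(1, 1, 2), c(2, 2, 4), order = 1L,
                  region_fun = function(x, y, z) ifelse(z < 1, "soft", "stiff"))
  fs <- m$facet_sets$interface
  expect_gt(nrow(fs$corners), 0)
  fa <- periofem:::face_adjacency(m$elems[, 1:4], m$region)
  ifc <- which(!is.na(fa$elem2) & fa$region1 != fa$region2)
  expect_identical(nrow(fs$corners), length(ifc))
  z <- m$nodes[fs$corners, 3]
  expect_true(all(abs(z - 1) < 1e-12))
})

test_that("the ligament shell is at least two elements thick", {
  m <- coarse_single_mesh()
  pdl <- match("pdl", m$region_names)
  # radial shell: two template rings; verify via thickness of single-element
  # span: each interface facet's owner element must not span the full shell
  v6 <- periofem:::fem_tet_volumes(m$nodes, m$elems[, 1:4])
  pdl_vol <- sum(v6[m$region == pdl])
  area <- sum(facet_geometry(m, "pdl_bone_interface")$area)
  # mean shell thickness (volume / interface area) must be ~0.1 mm
  expect_equal(pdl_vol / area, 0.1, tolerance = 0.15)
  # structural check: across the shell, the pdl_root and pdl_bone owners of
  # matching locations must differ (two distinct element layers)
  g1 <- facet_geometry(m, "pdl_root_interface")
  g2 <- facet_geometry(m, "pdl_bone_interface")
  expect_length(intersect(g1$elem, g2$elem), 0)
})

test_that("mesh generation is deterministic", {
  m1 <- generate_mesh(single_model(), size = 2.6, order = 1L)
  m2 <- generate_mesh(single_model(), size = 2.6, order = 1L)
  expect_identical(m1$nodes, m2$nodes)
  expect_identical(m1$elems, m2$elems)
  expect_identical(m1$region, m2$region)
})

test_that("total mesh volume is stable under refinement", {
  v <- vapply(c(2.6, 1.8), function(sz) {
    m <- generate_mesh(single_model(), size = sz, order = 1L)
    sum(periofem:::fem_tet_volumes(m$nodes, m$elems))
  }, 0)
  expect_lt(abs(diff(v)) / v[1], 0.005)
})

test_that("quality report counts and volumes are consistent", {
  m <- coarse_multi_mesh()
  q <- mesh_quality_report(m)
  tot <- q[q$region == "total", ]
  expect_identical(sum(q$n_elements[q$region != "total"]), tot$n_elements)
  expect_gt(tot$jacobian_min, 0)
  expect_equal(sum(q$volume_mm3[q$region != "total"]), tot$volume_mm3,
               tolerance = 1e-12)
})

test_that("a degenerate flat element is flagged by the quality report", {
  nodes <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(1, 1, 1e-12),
                 c(0, 0, 1))
  elems <- rbind(c(1L, 2L, 3L, 4L), c(1L, 2L, 3L, 5L))
  mesh <- structure(list(nodes = nodes, elems = elems, region = c(1L, 1L),
                         region_names = "block", order = 1L),
                    class = "fe_mesh")
  q <- mesh_quality_report(mesh)
  expect_lt(q$jacobian_min[q$region == "total"], 1e-10)
})

test_that("convergence study validates its inputs and flags convergence", {
  expect_error(convergence_study(single_model(), sizes = 2), "3 mesh sizes")
  expect_error(convergence_study(single_model(), sizes = c(1, 2, 3)),
               "decreasing")
  # a mesh-independent observable (uniform-stress patch) converges at once
  vals <- convergence_study(function(size) {
    ps <- patch_solve(get_material("dentin"),
                      n = rep(max(2L, round(1 / size)), 3), order = 2L)
    max(ps$stress[, 3])
  }, sizes = c(0.5, 0.34, 0.25))
  expect_true(attr(vals, "converged"))
  expect_lt(max(abs(vals$value - 1)), 1e-8)
})

test_that("cantilever deflection approaches beam theory under refinement", {
  E <- 18600
  tip <- function(n_len) {
    m <- block_mesh(c(10, 1, 1), c(n_len, 2, 2), order = 2L)
    sys <- assemble(m, materials = list(block = get_material("dentin")))
    sys <- apply_supports(sys, support = "xmin")
    f <- traction_load(m, "xmax", c(0, 0, 1))
    sol <- solve_system(sys, f)
    tipn <- which(abs(m$nodes[, 1] - 10) < 1e-9)
    mean(sol$u[3 * (tipn - 1) + 3])
  }
  delta_eb <- 1 * 10^3 / (3 * E * (1 / 12))
  d <- vapply(c(6, 12), tip, 0)
  err <- abs(d - delta_eb) / delta_eb
  expect_lt(err[2], err[1] + 1e-9)   # refinement moves toward beam theory
  expect_lt(err[2], 0.05)
})
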