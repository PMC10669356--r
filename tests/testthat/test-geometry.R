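# Parametric layered models: validation, layering rules, attachment
# reduction, symmetry and import/export.

test_that("invalid tooth parameters fail naming the violated constraint", {
  expect_error(tooth_params(root_length = -1), "root_length")
  expect_error(tooth_params("multi_rooted", furcation_depth_below_CEJ = 15),
               "furcation")
  expect_error(tooth_params(cortical_shell_thickness = 10), "cortical")
  expect_error(tooth_params("multi_rooted", inter_root_spread = 2),
               "inter_root_spread")
  expect_error(tooth_params(pulp_scale = 0.95), "pulp")
})

test_that("built models carry the frame and zero reduction", {
  model <- single_model()
  expect_identical(model$attachment_reduction, 0)
  ax <- root_axis(model)
  expect_equal(ax$axis, c(0, 0, 1))
  expect_equal(ax$origin, c(0, 0, 0))
  expect_null(furcation_roof_point(model))
  expect_equal(furcation_roof_point(multi_model()), c(0, 0, 3))
})

test_that("ligament thickness is 0.1 mm over the root surface", {
  for (mesh in list(coarse_single_mesh(), coarse_multi_mesh())) {
    th <- measure_pdl_thickness(mesh, n = 200, seed = 7)
    ok <- th > 0.08 & th < 0.12
    expect_gte(mean(ok), 0.95)
  }
})

test_that("models are mirror-symmetric about the mid-sagittal plane", {
  for (mesh in list(coarse_single_mesh(), coarse_multi_mesh())) {
    a <- mesh$nodes
    key <- function(x) {
      x <- round(x, 6)
      x[abs(x) < 5e-7] <- 0           # avoid -0.000000 labels
      paste(sprintf("%.6f", x[, 1]), sprintf("%.6f", x[, 2]),
            sprintf("%.6f", x[, 3]))
    }
    mirrored <- a
    mirrored[, 2] <- -mirrored[, 2]
    expect_true(all(key(mirrored) %in% key(a)))
  }
})

test_that("reduction 0 reproduces the identical mesh", {
  model <- single_model()
  m1 <- generate_mesh(model, size = 2.6, order = 1L)
  m2 <- generate_mesh(reduce_attachment(model, 0), size = 2.6, order = 1L)
  expect_identical(m1$nodes, m2$nodes)
  expect_identical(m1$elems, m2$elems)
  expect_identical(m1$region, m2$region)
})

test_that("reduction bounds are enforced", {
  model <- single_model()
  expect_error(reduce_attachment(model, -1), "non-negative")
  expect_error(reduce_attachment(model, 14), "exceeds")
})

test_that("interface area decreases strictly with attachment reduction", {
  model <- single_model()
  areas <- vapply(c(0, 2, 4, 6), function(red) {
    m <- generate_mesh(reduce_attachment(model, red), size = 2.6, order = 1L)
    sum(facet_geometry(m, "pdl_bone_interface")$area)
  }, 0)
  expect_true(all(diff(areas) < 0))
})

test_that("reduction removes ligament and crest bone coronal to the plane", {
  model <- single_model()
  red <- 3
  m <- generate_mesh(reduce_attachment(model, red), size = 2.6, order = 1L)
  rid <- match(c("pdl", "cortical_bone", "cancellous_bone"), m$region_names)
  ctr <- (m$nodes[m$elems[, 1], 3] + m$nodes[m$elems[, 2], 3] +
            m$nodes[m$elems[, 3], 3] + m$nodes[m$elems[, 4], 3]) / 4
  expect_true(all(ctr[m$region %in% rid] > red - 1e-9))
  # root surface (cementum) is still present above the reduction plane
  cem <- match("cementum", m$region_names)
  expect_true(any(ctr[m$region == cem] < red))
})

test_that("reduction past the furcation exposes the furcation roof", {
  model <- multi_model()
  m <- generate_mesh(reduce_attachment(model, 4), size = 2.6, order = 1L)
  g <- facet_geometry(m, "pdl_bone_interface")
  expect_true(all(g$centroid[, 3] > 4 - 1e-9))
  # the septum top at the furcation depth is now a free (exposed) surface
  fa <- periofem:::face_adjacency(m$elems[, 1:4], m$region)
  bnd <- which(is.na(fa$elem2))
  z <- (m$nodes[fa$a[bnd], 3] + m$nodes[fa$b[bnd], 3] +
          m$nodes[fa$c[bnd], 3]) / 3
  x <- (m$nodes[fa$a[bnd], 1] + m$nodes[fa$b[bnd], 1] +
          m$nodes[fa$c[bnd], 1]) / 3
  cem <- match("cementum", m$region_names)
  roof_free <- fa$region1[bnd] == cem & abs(z - 3) < 1e-6 & abs(x) < 1.5
  expect_true(any(roof_free))
})

test_that("multi-rooted models have a furcation roof ligament", {
  m <- coarse_multi_mesh()
  g <- facet_geometry(m, "pdl_bone_interface")
  roof <- furcation_roof_point(multi_model())
  d <- sqrt((g$centroid[, 1] - roof[1])^2 + (g$centroid[, 2] - roof[2])^2 +
              (g$centroid[, 3] - roof[3])^2)
  expect_true(any(d < 1.5))
})

test_that("tissue volumes agree with their extracted boundary surfaces", {
  m <- coarse_single_mesh()
  v6 <- periofem:::fem_tet_volumes(m$nodes, m$elems[, 1:4])
  model <- single_model()
  for (tissue in c("pdl", "dentin", "cancellous_bone")) {
    s <- tissue_surface(model, tissue, mesh = m)
    expect_true(is_watertight(s))
    rid <- match(tissue, m$region_names)
    expect_equal(surface_volume(s), sum(v6[m$region == rid]),
                 tolerance = 5e-3)
  }
})

test_that("surface export and import round-trip", {
  dir <- tempfile()
  model <- single_model()
  paths <- export_surfaces(model, dir, format = "ply", size = 2.6)
  expect_true(all(file.exists(paths)))
  imp <- import_surfaces(paths[c("dentin", "pdl")])
  expect_equal(sort(names(imp$surfaces)), c("dentin", "pdl"))
  orig <- tissue_surface(model, "dentin", size = 2.6)
  expect_equal(sort(imp$surfaces$dentin$vertices[, 1]),
               sort(orig$vertices[, 1]), tolerance = 1e-9)
})

test_that("import validation rejects bad inputs", {
  d <- tempfile(); dir.create(d)
  a <- file.path(d, "a.ply"); b <- file.path(d, "b.ply")
  write_surface(cube_surface(1), a)
  write_surface(cube_surface(1, shift = c(0.4, 0.4, 0.4)), b)
  expect_error(import_surfaces(list(dentin = a, pulp = b)), "overlap")
  big <- file.path(d, "big.ply")
  write_surface(cube_surface(2000), big)
  expect_error(import_surfaces(list(dentin = big)), "suspicious")
  open <- cylinder_surface(1, 1, 16, 2)
  open$faces <- open$faces[-1, ]
  op <- file.path(d, "open.ply")
  write_surface(open, op)
  expect_error(import_surfaces(list(dentin = op)), "watertight")
  expect_error(import_surfaces(list(a)), "named")
})

test_that("a missing ligament surface can be synthesized on import", {
  d <- tempfile(); dir.create(d)
  cyl <- cylinder_surface(3, 10, n_theta = 48, n_z = 8)
  p <- file.path(d, "dentin.ply")
  write_surface(cyl, p)
  imp <- import_surfaces(list(dentin = p), generate_pdl = TRUE)
  expect_true("pdl" %in% names(imp$surfaces))
  expect_true(is_watertight(imp$surfaces$pdl))
})

test_that("meshing is refused for imported (non-parametric) models", {
  d <- tempfile(); dir.create(d)
  p <- file.path(d, "dentin.ply")
  write_surface(cube_surface(5), p)
  imp <- import_surfaces(list(dentin = p))
  expect_error(generate_mesh(imp), "parametric")
})
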