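# Shared fixtures, computed lazily once per test run.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, fun) {
  if (!exists(name, envir = .fixtures)) assign(name, fun(), envir = .fixtures)
  get(name, envir = .fixtures)
}

# coarse meshes reused across tests
single_model <- function() build_tooth(tooth_params("single_rooted"))
multi_model <- function() build_tooth(tooth_params("multi_rooted"))

coarse_single_mesh <- function()
  fixture("coarse_single_mesh", function()
    generate_mesh(single_model(), size = 2.6, order = 1L))

coarse_multi_mesh <- function()
  fixture("coarse_multi_mesh", function()
    generate_mesh(multi_model(), size = 2.6, order = 1L))

# axis-aligned cube as a closed triangle surface (side a, corner at origin)
cube_surface <- function(a = 1, shift = c(0, 0, 0)) {
  v <- as.matrix(expand.grid(x = c(0, a), y = c(0, a), z = c(0, a)))
  v <- sweep(v, 2, shift, "+")
  f <- rbind(c(1, 3, 2), c(2, 3, 4),      # z = 0
             c(5, 6, 7), c(6, 8, 7),      # z = a
             c(1, 2, 5), c(2, 6, 5),      # y = 0
             c(3, 7, 4), c(4, 7, 8),      # y = a
             c(1, 5, 3), c(3, 5, 7),      # x = 0
             c(2, 4, 6), c(4, 8, 6))      # x = a
  tri_surface(v, f)
}

# statically determinate uniaxial patch configuration on a block mesh:
# uniform traction sigma on zmax, minimal constraints, returns element
# stresses and the system
patch_solve <- function(material, n = c(2, 2, 2), order = 2L, sigma = 1) {
  m <- block_mesh(c(1, 1, 1), n, order = order)
  sys <- assemble(m, materials = setNames(list(material), "block"))
  base <- which(abs(m$nodes[, 3]) < 1e-12)
  sys <- apply_supports(sys, nodes = base, components = 3)
  origin <- which(rowSums(abs(m$nodes)) < 1e-12)
  sys <- suppressWarnings(apply_supports(sys, nodes = origin, components = 1:2))
  other <- which(abs(m$nodes[, 1]) < 1e-12 & abs(m$nodes[, 2] - 1) < 1e-12 &
                   abs(m$nodes[, 3]) < 1e-12)
  sys <- suppressWarnings(apply_supports(sys, nodes = other, components = 1))
  f <- traction_load(m, "zmax", c(0, 0, sigma))
  sol <- solve_system(sys, f)
  stress <- periofem:::fem_element_stress(m$nodes, m$elems, sol$u, sys$E, sys$nu)
  list(mesh = m, sys = sys, sol = sol, stress = stress)
}

# measure ligament shell thickness by casting rays from the root-side
# interface across the ligament region to its outer boundary (bone, or a
# free surface where the template leaves the shell unbacked)
measure_pdl_thickness <- function(mesh, n = 200, seed = 42) {
  set.seed(seed)
  g <- facet_geometry(mesh, "pdl_root_interface")
  pdl <- match("pdl", mesh$region_names)
  keep <- which(mesh$region == pdl)
  fa <- periofem:::face_adjacency(mesh$elems[keep, 1:4, drop = FALSE],
                                  rep(1L, length(keep)))
  bnd <- as.matrix(fa[is.na(fa$elem2), c("a", "b", "c")])
  # drop the inner (root-side) faces so rays measure the outward span
  keyf <- function(m3) paste(pmin(m3[, 1], m3[, 2], m3[, 3]),
                             m3[, 1] + m3[, 2] + m3[, 3],
                             pmax(m3[, 1], m3[, 2], m3[, 3]))
  inner <- keyf(mesh$facet_sets$pdl_root_interface$corners)
  outer <- bnd[!(keyf(bnd) %in% inner), , drop = FALSE]
  surf <- tri_surface(mesh$nodes, outer)
  idx <- sample.int(nrow(g$centroid), n, replace = TRUE, prob = g$area)
  vapply(idx, function(i) {
    # pdl_root normals point from the ligament into the root; cast outward
    periofem:::ray_surface_distance(g$centroid[i, ], -g$normal[i, ], surf)
  }, 0)
}
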