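#' Triangulated surfaces
#'
#' Closed (watertight) triangle meshes represent per-tissue boundaries.
#' Vertices are an `n x 3` matrix in mm; faces an `m x 3` integer matrix of
#' vertex indices, oriented counter-clockwise seen from outside, so the
#' divergence theorem gives the enclosed volume.
#'
#' @param vertices numeric `n x 3` matrix.
#' @param faces integer `m x 3` matrix (1-based).
#' @return object of class `tri_surface`.
#' @export
tri_surface <- function(vertices, faces) {
  vertices <- as.matrix(vertices)
  faces <- matrix(as.integer(as.matrix(faces)), ncol = 3)
  stopifnot(ncol(vertices) == 3, ncol(faces) == 3)
  if (any(faces < 1L) || any(faces > nrow(vertices)))
    stop("face indices out of range")
  structure(list(vertices = vertices, faces = faces), class = "tri_surface")
}

#' @export
print.tri_surface <- function(x, ...) {
  cat(sprintf("<tri_surface> %d vertices, %d faces, %s\n",
              nrow(x$vertices), nrow(x$faces),
              if (is_watertight(x)) "watertight" else "open"))
  invisible(x)
}

face_corners <- function(s) {
  list(a = s$vertices[s$faces[, 1], , drop = FALSE],
       b = s$vertices[s$faces[, 2], , drop = FALSE],
       c = s$vertices[s$faces[, 3], , drop = FALSE])
}

cross3 <- function(u, v) {
  cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
        u[, 3] * v[, 1] - u[, 1] * v[, 3],
        u[, 1] * v[, 2] - u[, 2] * v[, 1])
}

#' Surface area of a triangle mesh
#' @param s a `tri_surface`.
#' @return total area (mm^2).
#' @export
surface_area <- function(s) {
  fc <- face_corners(s)
  n <- cross3(fc$b - fc$a, fc$c - fc$a)
  sum(sqrt(rowSums(n^2))) / 2
}

#' Enclosed volume of a closed triangle mesh
#'
#' Signed volume by the divergence theorem; positive for outward-oriented
#' closed surfaces.
#' @param s a `tri_surface`.
#' @return volume (mm^3).
#' @export
surface_volume <- function(s) {
  fc <- face_corners(s)
  sum(rowSums(fc$a * cross3(fc$b, fc$c))) / 6
}

#' Watertightness test
#'
#' A surface is watertight when every undirected edge is used by exactly two
#' faces, once in each direction (consistent orientation).
#' @param s a `tri_surface`.
#' @return logical.
#' @export
is_watertight <- function(s) {
  f <- s$faces
  he <- rbind(f[, 1:2], f[, 2:3], f[, c(3, 1)])
  n <- nrow(s$vertices)
  key_dir <- (he[, 1] - 1) * n + he[, 2]
  key_und <- (pmin(he[, 1], he[, 2]) - 1) * n + pmax(he[, 1], he[, 2])
  tu <- table(key_und)
  all(tu == 2L) && !anyDuplicated(key_dir)
}

#' Area-weighted vertex normals
#'
#' @param s a `tri_surface`.
#' @param face_mask optional logical mask over faces: normals are averaged
#'   only over masked faces (vertices touched by no masked face fall back to
#'   all incident faces).  Used to keep offset directions radial at shell
#'   rims.
#' @return `n x 3` matrix of unit normals (zero rows for unused vertices).
#' @export
vertex_normals <- function(s, face_mask = NULL) {
  fc <- face_corners(s)
  fn <- cross3(fc$b - fc$a, fc$c - fc$a)  # area-weighted
  accumulate <- function(idx) {
    out <- matrix(0, nrow(s$vertices), 3)
    for (k in 1:3) {
      rs <- rowsum(fn[idx, , drop = FALSE], group = s$faces[idx, k])
      rows <- as.integer(rownames(rs))
      out[rows, ] <- out[rows, ] + rs
    }
    out
  }
  nall <- accumulate(seq_len(nrow(s$faces)))
  if (!is.null(face_mask)) {
    nm <- accumulate(which(face_mask))
    use <- rowSums(nm^2) > 0
    nall[use, ] <- nm[use, ]
  }
  len <- sqrt(rowSums(nall^2))
  len[len == 0] <- 1
  nall / len
}

#' Offset a surface along vertex normals
#'
#' @param s a `tri_surface`.
#' @param thickness offset distance in mm (scalar or per-vertex); positive
#'   is outward.
#' @param region optional vertex mask (logical vector or
#'   `function(vertices) -> logical`); unmasked vertices stay in place and
#'   masked-vertex normals are computed from faces lying fully inside the
#'   region, so shell rims stay tangent to the untouched part.
#' @param check detect local self-intersection (triangle normal flips after
#'   offsetting) and fail with the location.
#' @return the offset `tri_surface`.
#' @export
offset_surface <- function(s, thickness, region = NULL, check = TRUE) {
  nv <- nrow(s$vertices)
  if (is.function(region)) region <- region(s$vertices)
  if (is.null(region)) region <- rep(TRUE, nv)
  stopifnot(length(region) == nv)
  th <- rep_len(thickness, nv)
  th[!region] <- 0
  face_mask <- region[s$faces[, 1]] & region[s$faces[, 2]] & region[s$faces[, 3]]
  nrm <- vertex_normals(s, face_mask = if (any(face_mask)) face_mask else NULL)
  out <- s
  out$vertices <- s$vertices + nrm * th
  if (check) {
    fc0 <- face_corners(s); fc1 <- face_corners(out)
    n0 <- cross3(fc0$b - fc0$a, fc0$c - fc0$a)
    n1 <- cross3(fc1$b - fc1$a, fc1$c - fc1$a)
    bad <- which(rowSums(n0 * n1) <= 0 & rowSums(n0^2) > 0)
    if (length(bad)) {
      ctr <- (fc0$a[bad[1], ] + fc0$b[bad[1], ] + fc0$c[bad[1], ]) / 3
      stop(sprintf(paste0("offset self-intersects: %d triangle(s) flip, first near ",
                          "(%.3f, %.3f, %.3f); reduce thickness or refine locally"),
                   length(bad), ctr[1], ctr[2], ctr[3]))
    }
  }
  out
}

#' Create the periodontal-ligament shell from a root surface
#'
#' Offsets the root surface outward by the ligament thickness and returns
#' the shell enclosed between the original and the offset surface.
#'
#' @param root_surface watertight `tri_surface` of the root.
#' @param thickness shell thickness in mm (0.1 by default).
#' @param region optional vertex mask restricting the offset to the part of
#'   the surface carrying ligament (e.g. below the CEJ); see
#'   [offset_surface()].
#' @return object of class `tissue_shell`: list with `inner`, `outer`
#'   surfaces, `thickness`, and the shell `volume` (mm^3).
#' @export
create_pdl_layer <- function(root_surface, thickness = 0.1, region = NULL) {
  if (!is.numeric(thickness) || length(thickness) != 1 || thickness <= 0)
    stop("shell thickness must be a positive scalar (got ", thickness, ")")
  if (!is_watertight(root_surface))
    stop("root surface must be watertight")
  outer <- offset_surface(root_surface, thickness, region = region)
  structure(list(inner = root_surface, outer = outer, thickness = thickness,
                 volume = surface_volume(outer) - surface_volume(root_surface)),
            class = "tissue_shell")
}

#' Cementum thickness profile
#'
#' Stepwise thickness over normalized root height `h` (0 at the CEJ, 1 at
#' the apex): 50 um in the cervical third, 100 um in the middle third,
#' 150 um in the apical third.
#' @param h normalized height in `[0, 1]` (vectorized).
#' @return thickness in mm.
#' @export
cementum_thickness <- function(h) {
  stopifnot(all(h >= -1e-9 & h <= 1 + 1e-9))
  ifelse(h < 1 / 3, 0.05, ifelse(h < 2 / 3, 0.10, 0.15))
}

#' Create the graded cementum shell of a root
#'
#' The cementum lies between dentin and PDL: the shell between the root
#' surface and its inward offset, with stepwise thickness 50/100/150 um over
#' the cervical/middle/apical thirds of the root height.
#'
#' @param root_surface watertight `tri_surface` of the root (CEJ to apex).
#' @param cej_curve numeric matrix of points on the CEJ (its centroid
#'   anchors the root axis).
#' @param apex_point numeric length-3, the root apex.
#' @param region optional vertex mask (defaults to all vertices).
#' @return a `tissue_shell` with `outer` = root surface and `inner` the
#'   graded inward offset; carries a `thickness_fun` of normalized height.
#' @export
create_cementum_layer <- function(root_surface, cej_curve, apex_point,
                                  region = NULL) {
  cej_curve <- as.matrix(cej_curve)
  origin <- colMeans(cej_curve)
  axis <- as.numeric(apex_point) - origin
  L <- sqrt(sum(axis^2))
  if (L < 1e-6)
    stop("apex point lies on the CEJ plane: root height is zero")
  axis <- axis / L
  h <- pmin(1, pmax(0, ((sweep(root_surface$vertices, 2, origin)) %*% axis)[, 1] / L))
  th <- cementum_thickness(h)
  inner <- offset_surface(root_surface, -th, region = region)
  structure(list(inner = inner, outer = root_surface,
                 thickness = NA_real_, thickness_fun = cementum_thickness,
                 volume = surface_volume(root_surface) - surface_volume(inner)),
            class = "tissue_shell")
}

#' @export
print.tissue_shell <- function(x, ...) {
  cat(sprintf("<tissue_shell> volume %.4f mm^3%s\n", x$volume,
              if (is.na(x$thickness)) " (graded thickness)"
              else sprintf(", thickness %g mm", x$thickness)))
  invisible(x)
}

# ---- point / ray queries ---------------------------------------------------

# Smallest positive distance from `origin` along `dir` to the surface
# (Moller-Trumbore over all faces); Inf when the ray misses.
ray_surface_distance <- function(origin, dir, s, eps = 1e-12) {
  fc <- face_corners(s)
  e1 <- fc$b - fc$a
  e2 <- fc$c - fc$a
  dirm <- matrix(dir, nrow(e1), 3, byrow = TRUE)
  p <- cross3(dirm, e2)
  det <- rowSums(e1 * p)
  ok <- abs(det) > eps
  tvec <- sweep(fc$a, 2, origin, "-") * -1
  u <- rowSums(tvec * p) / det
  q <- cross3(tvec, e1)
  v <- rowSums(dirm * q) / det
  t <- rowSums(e2 * q) / det
  hit <- ok & u >= -1e-9 & v >= -1e-9 & (u + v) <= 1 + 1e-9 & t > 1e-9
  if (!any(hit)) return(Inf)
  min(t[hit])
}

# Parity test: is point strictly inside closed surface s?
point_in_surface <- function(point, s) {
  dir <- c(0.57735026918962584, 0.26726124191242440, 0.77459666924148340)
  fc <- face_corners(s)
  e1 <- fc$b - fc$a
  e2 <- fc$c - fc$a
  dirm <- matrix(dir, nrow(e1), 3, byrow = TRUE)
  p <- cross3(dirm, e2)
  det <- rowSums(e1 * p)
  ok <- abs(det) > 1e-12
  tvec <- sweep(fc$a, 2, point)
  u <- rowSums(-tvec * p) / det
  q <- cross3(-tvec, e1)
  v <- rowSums(dirm * q) / det
  t <- rowSums(e2 * q) / det
  hits <- sum(ok & u >= 0 & v >= 0 & (u + v) <= 1 & t > 1e-9, na.rm = TRUE)
  (hits %% 2) == 1
}

# ---- primitive surfaces (verification oracles) -----------------------------

#' Closed cylinder surface
#'
#' @param radius,height cylinder dimensions (mm); axis +z, base at z = 0.
#' @param n_theta,n_z angular and axial subdivisions.
#' @return watertight `tri_surface`.
#' @export
cylinder_surface <- function(radius, height, n_theta = 64, n_z = 20) {
  th <- seq(0, 2 * pi, length.out = n_theta + 1)[-(n_theta + 1)]
  zs <- seq(0, height, length.out = n_z + 1)
  ring <- cbind(radius * cos(th), radius * sin(th))
  verts <- do.call(rbind, lapply(zs, function(z) cbind(ring, z)))
  id <- function(i, k) (k - 1) * n_theta + i          # i: angular, k: level
  faces <- list()
  for (k in seq_len(n_z)) {
    i <- seq_len(n_theta); j <- c(seq_len(n_theta)[-1], 1L)
    faces[[length(faces) + 1]] <- cbind(id(i, k), id(j, k), id(j, k + 1))
    faces[[length(faces) + 1]] <- cbind(id(i, k), id(j, k + 1), id(i, k + 1))
  }
  nb <- nrow(verts)
  verts <- rbind(verts, c(0, 0, 0), c(0, 0, height))
  i <- seq_len(n_theta); j <- c(seq_len(n_theta)[-1], 1L)
  faces[[length(faces) + 1]] <- cbind(id(j, 1), id(i, 1), nb + 1L)        # bottom
  faces[[length(faces) + 1]] <- cbind(id(i, n_z + 1), id(j, n_z + 1), nb + 2L)
  tri_surface(verts, do.call(rbind, faces))
}

#' Closed hemisphere surface (dome plus base disk)
#'
#' @param radius hemisphere radius (mm); dome over z >= 0.
#' @param n_theta,n_phi angular subdivisions.
#' @return watertight `tri_surface`.
#' @export
hemisphere_surface <- function(radius, n_theta = 64, n_phi = 24) {
  th <- seq(0, 2 * pi, length.out = n_theta + 1)[-(n_theta + 1)]
  ph <- seq(0, pi / 2, length.out = n_phi + 1)[-(n_phi + 1)]  # 0 = equator
  verts <- do.call(rbind, lapply(ph, function(p)
    cbind(radius * cos(p) * cos(th), radius * cos(p) * sin(th),
          radius * sin(p))))
  id <- function(i, k) (k - 1) * n_theta + i
  faces <- list()
  for (k in seq_len(n_phi - 1)) {
    i <- seq_len(n_theta); j <- c(seq_len(n_theta)[-1], 1L)
    faces[[length(faces) + 1]] <- cbind(id(i, k), id(j, k), id(j, k + 1))
    faces[[length(faces) + 1]] <- cbind(id(i, k), id(j, k + 1), id(i, k + 1))
  }
  nb <- nrow(verts)
  verts <- rbind(verts, c(0, 0, radius), c(0, 0, 0))
  i <- seq_len(n_theta); j <- c(seq_len(n_theta)[-1], 1L)
  faces[[length(faces) + 1]] <- cbind(id(i, n_phi), id(j, n_phi), nb + 1L)  # pole cap
  faces[[length(faces) + 1]] <- cbind(id(j, 1), id(i, 1), nb + 2L)          # base
  tri_surface(verts, do.call(rbind, faces))
}
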