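# Cross-section template for the layered tooth model.
#
# The template is a fixed 2D triangulation of the bone-block cross-section:
# a tensor background grid with one square hole per root, each hole filled
# by an O-grid "port" (a square-to-circle transition ring plus concentric
# tissue rings down to the pulp centre).  Every z-plane of the volume mesh
# uses the same connectivity; only the ring radii move with z, so tissue
# interfaces (pulp/dentin/cementum/PDL) are exact template surfaces and the
# extruded tetrahedral mesh is conforming across all of them.

RING_NAMES <- c("t1", "pdlo", "pdlm", "cemo", "cemi", "d1", "pulp")
BAND_NAMES <- c("trans_a", "trans_b", "pdl_a", "pdl_b", "cem", "den_a", "den_b")

build_template <- function(model, size) {
  p <- model$params
  hs <- p$port_half_side
  W <- p$bone_block_dims[1]; D <- p$bone_block_dims[2]
  multi <- model$tooth_class == "multi_rooted"
  centers <- model$centers
  Ns <- max(3L, as.integer(round(2 * hs / size)))
  cell <- 2 * hs / Ns

  margin_lines <- function(from, to) {
    # graded lines from |from| outward to |to| (positive side)
    nm <- max(2L, ceiling((to - from) / (1.35 * cell)))
    seq(from, to, length.out = nm + 1)[-1]
  }
  hole_lines <- function(cx) cx + seq(-hs, hs, length.out = Ns + 1)
  if (multi) {
    cc <- centers[2, 1]                       # +x root centre
    sepw <- 2 * (cc - hs)
    nsep <- max(1L, round(sepw / cell))
    sep <- seq(-(cc - hs), cc - hs, length.out = nsep + 1)
    xg <- sort(unique(round(c(hole_lines(-cc), hole_lines(cc), sep,
                              margin_lines(cc + hs, W / 2),
                              -margin_lines(cc + hs, W / 2)), 9)))
  } else {
    xg <- sort(unique(round(c(hole_lines(0),
                              margin_lines(hs, W / 2),
                              -margin_lines(hs, W / 2)), 9)))
  }
  yflank <- if (multi) c(-hs - 0.4, hs + 0.4) else numeric(0)
  yg <- sort(unique(round(c(seq(-hs, hs, length.out = Ns + 1), yflank,
                            margin_lines(hs, D / 2),
                            -margin_lines(hs, D / 2)), 9)))

  nx <- length(xg); ny <- length(yg)
  in_hole_strict <- function(x, y) {
    inside <- rep(FALSE, length(x))
    for (k in seq_len(nrow(centers)))
      inside <- inside | (x > centers[k, 1] - hs + 1e-9 &
                          x < centers[k, 1] + hs - 1e-9 &
                          y > centers[k, 2] - hs + 1e-9 &
                          y < centers[k, 2] + hs - 1e-9)
    inside
  }
  gx <- rep(xg, times = ny); gy <- rep(yg, each = nx)
  keep <- !in_hole_strict(gx, gy)
  idx <- matrix(NA_integer_, nx, ny)
  idx[keep] <- seq_len(sum(keep))
  bg_xy <- cbind(gx[keep], gy[keep])
  n_bg <- nrow(bg_xy)

  # ordered CCW perimeter of a hole (bottom, right, top, left)
  perimeter_ids <- function(cx, cy) {
    xi <- which(abs(xg - (cx - hs)) < 1e-9):which(abs(xg - (cx + hs)) < 1e-9)
    yi <- which(abs(yg - (cy - hs)) < 1e-9):which(abs(yg - (cy + hs)) < 1e-9)
    stopifnot(length(xi) == Ns + 1, length(yi) == Ns + 1)
    bottom <- idx[xi, yi[1]]
    right  <- idx[xi[Ns + 1], yi]
    top    <- idx[rev(xi), yi[Ns + 1]]
    left   <- idx[xi[1], rev(yi)]
    ids <- c(bottom, right[-1], top[-1], left[-1])
    ids[-length(ids)]                          # drop repeated start corner
  }

  n_theta <- 4L * Ns
  nring <- length(RING_NAMES)
  ports <- vector("list", nrow(centers))
  ring_port <- ring_name <- integer(0)
  ring_Q <- ring_u <- NULL
  next_id <- n_bg
  for (k in seq_len(nrow(centers))) {
    per <- perimeter_ids(centers[k, 1], centers[k, 2])
    stopifnot(length(per) == n_theta, !anyNA(per))
    Q <- bg_xy[per, , drop = FALSE]
    th <- atan2(Q[, 2] - centers[k, 2], Q[, 1] - centers[k, 1])
    u <- cbind(cos(th), sin(th))
    ring_ids <- matrix(0L, nring, n_theta)
    for (r in seq_len(nring)) {
      ring_ids[r, ] <- next_id + seq_len(n_theta)
      next_id <- next_id + n_theta
      ring_port <- c(ring_port, rep(k, n_theta))
      ring_name <- c(ring_name, rep(r, n_theta))
      ring_Q <- rbind(ring_Q, Q)
      ring_u <- rbind(ring_u, u)
    }
    center_id <- next_id + 1L
    next_id <- center_id
    ports[[k]] <- list(center = centers[k, ], perim = per, theta = th,
                       u = u, ring_ids = ring_ids, center_id = center_id,
                       facing_edge_x = if (multi)
                         centers[k, 1] - sign(centers[k, 1]) * hs else NA_real_)
  }
  NS <- next_id

  # ---- triangles -----------------------------------------------------------
  tri <- list(); kind <- band <- character(0)
  port_of <- sector <- integer(0)
  inward <- septum <- cortical <- flank <- guard <- logical(0)
  ccx <- ccy <- numeric(0)

  add <- function(t3, kd, bd, pt, sec, inw, sep, cor, flk, grd, cx, cy) {
    tri[[length(tri) + 1]] <<- t3
    nadd <- nrow(t3)
    kind <<- c(kind, rep(kd, nadd)); band <<- c(band, rep(bd, nadd))
    port_of <<- c(port_of, rep(pt, nadd)); sector <<- c(sector, rep(sec, nadd))
    inward <<- c(inward, rep(inw, nadd)); septum <<- c(septum, rep(sep, nadd))
    cortical <<- c(cortical, rep(cor, nadd))
    flank <<- c(flank, rep(flk, nadd)); guard <<- c(guard, rep(grd, nadd))
    ccx <<- c(ccx, rep(cx, nadd)); ccy <<- c(ccy, rep(cy, nadd))
  }

  tcort <- p$cortical_shell_thickness
  for (ix in seq_len(nx - 1)) for (iy in seq_len(ny - 1)) {
    cx <- (xg[ix] + xg[ix + 1]) / 2; cy <- (yg[iy] + yg[iy + 1]) / 2
    if (in_hole_strict(cx, cy)) next
    n00 <- idx[ix, iy]; n10 <- idx[ix + 1, iy]
    n11 <- idx[ix + 1, iy + 1]; n01 <- idx[ix, iy + 1]
    sep <- multi && abs(cx) < centers[2, 1] - hs + 1e-9 && abs(cy) < hs - 1e-9
    # flank strip: first cell row outside the septum in y (extended one cell
    # past the hole corners); kept free in the root-trunk zone so the trunk
    # web never bonds to bone directly, not even through corner nodes
    flk <- multi && abs(cx) < centers[2, 1] - hs + cell + 1e-9 &&
      abs(cy) > hs - 1e-9 && abs(cy) < hs + 0.4 + 1e-9
    cor <- (abs(cx) > W / 2 - tcort) || (abs(cy) > D / 2 - tcort)
    add(rbind(c(n00, n10, n11), c(n00, n11, n01)), "bg", "bg", 0L, 0L,
        FALSE, sep, cor, flk, FALSE, cx, cy)
  }

  for (k in seq_len(nrow(centers))) {
    po <- ports[[k]]
    nxt <- c(seq_len(n_theta)[-1], 1L)
    prv <- c(n_theta, seq_len(n_theta)[-n_theta])
    inw_sec <- rep(FALSE, n_theta)
    if (multi) {
      onedge <- abs(bg_xy[po$perim, 1] - po$facing_edge_x) < 1e-9
      inw_sec <- onedge & onedge[nxt]
    }
    # guard sectors flank the inward wedge; their bone transition cells are
    # kept free in the trunk zone (same embrasure as the bg flank strip)
    grd_sec <- !inw_sec & (inw_sec[nxt] | inw_sec[prv])
    rings <- rbind(po$perim, po$ring_ids)      # (nring+1) x n_theta, outer->inner
    for (b in seq_len(nring)) {
      o <- rings[b, ]; i <- rings[b + 1, ]
      for (s in seq_len(n_theta)) {
        s2 <- nxt[s]
        add(rbind(c(o[s], o[s2], i[s2]), c(o[s], i[s2], i[s])),
            "band", BAND_NAMES[b], k, s, inw_sec[s], FALSE, FALSE, FALSE,
            grd_sec[s], NA, NA)
      }
    }
    inner <- po$ring_ids[nring, ]
    for (s in seq_len(n_theta))
      add(rbind(c(inner[s], inner[nxt[s]], po$center_id)),
          "fan", "pulp_fan", k, s, inw_sec[s], FALSE, FALSE, FALSE, FALSE,
          NA, NA)
  }

  tris <- do.call(rbind, tri)
  attrs <- data.frame(kind = kind, band = band, port = port_of,
                      sector = sector, inward = inward, septum = septum,
                      cortical_xy = cortical, flank = flank, guard = guard,
                      cx = ccx, cy = ccy,
                      stringsAsFactors = FALSE)

  tpl <- list(xg = xg, yg = yg, bg_xy = bg_xy, n_bg = n_bg, NS = NS,
              ports = ports, n_theta = n_theta, Ns = Ns,
              ring_port = ring_port, ring_name = ring_name,
              ring_Q = ring_Q, ring_u = ring_u,
              tris = tris, attrs = attrs, multi = multi)

  # orient all triangles CCW using a representative root-plane configuration
  xy <- template_coords(tpl, p$root_length / 2, p)
  a <- xy[tris[, 1], ]; b <- xy[tris[, 2], ]; c_ <- xy[tris[, 3], ]
  ar <- (b[, 1] - a[, 1]) * (c_[, 2] - a[, 2]) -
        (b[, 2] - a[, 2]) * (c_[, 1] - a[, 1])
  flip <- ar < 0
  if (any(flip)) tpl$tris[flip, ] <- tpl$tris[flip, c(1, 3, 2)]
  if (any(ar == 0)) stop("degenerate template triangle")
  tpl
}

# Node coordinates of the cross-section at plane z.
template_coords <- function(tpl, z, params) {
  xy <- matrix(0, tpl$NS, 2)
  xy[seq_len(tpl$n_bg), ] <- tpl$bg_xy
  R <- plane_radii(params, z)
  nring <- length(RING_NAMES)
  pos <- tpl$n_bg
  for (k in seq_along(tpl$ports)) {
    po <- tpl$ports[[k]]
    C <- po$center
    nt <- tpl$n_theta
    for (r in seq_len(nring)) {
      ids <- po$ring_ids[r, ]
      nm <- RING_NAMES[r]
      if (nm == "t1") {
        circ <- cbind(C[1] + R[["pdlo"]] * po$u[, 1],
                      C[2] + R[["pdlo"]] * po$u[, 2])
        xy[ids, ] <- 0.5 * (tpl$bg_xy[po$perim, , drop = FALSE] + circ)
      } else {
        xy[ids, ] <- cbind(C[1] + R[[nm]] * po$u[, 1],
                           C[2] + R[[nm]] * po$u[, 2])
      }
    }
    xy[po$center_id, ] <- C
  }
  xy
}
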