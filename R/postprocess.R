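# Readout extraction: contact pressure on the PDL-bone interface, stress
# invariants, anatomical-zone summaries, and failure detection.

#' Contact pressure on a tied interface
#'
#' Normal traction across the (bonded) interface, evaluated from the
#' PDL-side element stress: for facet normal n pointing from the ligament
#' into the bone, the transmitted traction is t = sigma . n and the contact
#' pressure is p = -n . sigma . n, so compression is positive and tension
#' negative.
#'
#' @param solution a `solution_field`.
#' @param mesh the mesh the solution was computed on (defaults to
#'   `solution$mesh`).
#' @param interface facet-set name (default `"pdl_bone_interface"`).
#' @return object of class `contact_pressure_map`: per-facet table
#'   (centroid, area, normal traction vector, pressure) plus summary fields
#'   `peak`, `p99`, `mean` (area-weighted, MPa), `total_axial_N` (axial
#'   component of the integrated traction) and `equilibrium_gap` (relative
#'   mismatch against the applied axial load).
#' @export
contact_pressure <- function(solution, mesh = solution$mesh,
                             interface = "pdl_bone_interface") {
  fs <- mesh$facet_sets[[interface]]
  if (is.null(fs) || nrow(fs$corners) == 0)
    stop("interface facet set '", interface, "' is empty")
  g <- facet_geometry(mesh, interface)
  S <- solution$stress[g$elem, , drop = FALSE]     # Voigt xx,yy,zz,xy,yz,xz
  n <- g$normal                                    # ligament -> bone
  # traction transmitted onto the bone: t = -sigma . n (PDL-side stress);
  # its normal component n . t = -n.sigma.n is the contact pressure,
  # positive in compression.
  tx <- -(S[, 1] * n[, 1] + S[, 4] * n[, 2] + S[, 6] * n[, 3])
  ty <- -(S[, 4] * n[, 1] + S[, 2] * n[, 2] + S[, 5] * n[, 3])
  tz <- -(S[, 6] * n[, 1] + S[, 5] * n[, 2] + S[, 3] * n[, 3])
  pressure <- tx * n[, 1] + ty * n[, 2] + tz * n[, 3]
  w <- g$area / sum(g$area)
  ord <- order(pressure)
  cw <- cumsum(w[ord])
  p99 <- pressure[ord][which(cw >= 0.99)[1]]
  total_axial <- sum(tz * g$area)
  applied_axial <- solution$applied_force[3]
  gap <- if (abs(applied_axial) > 0)
    abs(total_axial - applied_axial) / abs(applied_axial) else NA_real_
  structure(list(
    facets = data.frame(x = g$centroid[, 1], y = g$centroid[, 2],
                        z = g$centroid[, 3], area = g$area,
                        tx = tx, ty = ty, tz = tz, pressure = pressure),
    interface = interface,
    peak = max(pressure), p99 = p99, mean = sum(w * pressure),
    min = min(pressure),
    area = sum(g$area), total_axial_N = total_axial,
    equilibrium_gap = gap
  ), class = "contact_pressure_map")
}

#' @export
print.contact_pressure_map <- function(x, ...) {
  cat(sprintf("<contact_pressure_map> %s: %d facets, %.2f mm^2\n",
              x$interface, nrow(x$facets), x$area))
  cat(sprintf("  peak %.4f MPa (p99 %.4f), mean %.4f MPa, axial transmitted %.2f N (gap %.2f%%)\n",
              x$peak, x$p99, x$mean, x$total_axial_N,
              100 * x$equilibrium_gap))
  invisible(x)
}

#' Von Mises and principal stresses per element
#'
#' Closed-form eigen-decomposition of the symmetric 3x3 stress tensor
#' (trigonometric method), vectorized over elements.
#'
#' @param solution a `solution_field` (or a stress matrix in Voigt order
#'   xx, yy, zz, xy, yz, xz).
#' @return data.frame with `von_mises`, `s1 >= s2 >= s3` (MPa).
#' @export
stress_invariants <- function(solution) {
  S <- if (inherits(solution, "solution_field")) solution$stress else solution
  sxx <- S[, 1]; syy <- S[, 2]; szz <- S[, 3]
  sxy <- S[, 4]; syz <- S[, 5]; sxz <- S[, 6]
  vm <- sqrt(0.5 * ((sxx - syy)^2 + (syy - szz)^2 + (szz - sxx)^2) +
               3 * (sxy^2 + syz^2 + sxz^2))
  q <- (sxx + syy + szz) / 3
  dxx <- sxx - q; dyy <- syy - q; dzz <- szz - q
  p2 <- (dxx^2 + dyy^2 + dzz^2) / 2 + sxy^2 + syz^2 + sxz^2  # J2
  p <- sqrt(pmax(p2 / 3, 0))
  # det of the deviator
  detd <- dxx * (dyy * dzz - syz^2) - sxy * (sxy * dzz - syz * sxz) +
    sxz * (sxy * syz - dyy * sxz)
  r <- ifelse(p > 0, detd / 2 / p^3, 0)
  r <- pmin(pmax(r, -1), 1)
  phi <- acos(r) / 3
  s1 <- q + 2 * p * cos(phi)
  s3 <- q + 2 * p * cos(phi + 2 * pi / 3)
  s2 <- 3 * q - s1 - s3
  data.frame(von_mises = vm, s1 = s1, s2 = s2, s3 = s3)
}

#' Regional summary of interface contact pressure
#'
#' Partitions the (remaining) PDL-bone interface into anatomical zones and
#' summarizes the pressure per zone.  Zones: `furcation_roof` (within
#' 1.5 mm of the furcation roof point, multi-rooted only), `apical` (the
#' apical 2 mm of the interface), `cervical` (the coronal 25 % of the
#' remaining interface height), `mid_root` (the rest); assignment follows
#' that priority, so the zones partition the interface and their areas sum
#' to the interface area.  After attachment reduction the cervical band is
#' the coronal band of the remaining interface.
#'
#' @param pressure a `contact_pressure_map`.
#' @param model the `tooth_model` the mesh was built from.
#' @param apical_cap_mm apical zone extent (mm).
#' @param cervical_fraction coronal fraction of remaining height.
#' @param furcation_radius_mm furcation-roof zone radius (mm).
#' @return object of class `regional_summary`: data.frame with one row per
#'   zone: `area_mm2`, `peak_MPa`, `mean_MPa` (area-weighted) and
#'   `axial_share` (zone share of the transmitted axial load).
#' @export
regional_summary <- function(pressure, model, apical_cap_mm = 2,
                             cervical_fraction = 0.25,
                             furcation_radius_mm = 1.5) {
  fx <- pressure$facets
  if (nrow(fx) == 0) stop("empty interface: no remaining support")
  zmin <- min(fx$z); zmax <- max(fx$z)
  h <- zmax - zmin
  zone <- rep("mid_root", nrow(fx))
  roof <- furcation_roof_point(model)
  if (!is.null(roof) && model$attachment_reduction <=
        model$params$furcation_depth_below_CEJ) {
    d <- sqrt((fx$x - roof[1])^2 + (fx$y - roof[2])^2 + (fx$z - roof[3])^2)
    zone[d <= furcation_radius_mm] <- "furcation_roof"
  }
  zone[zone == "mid_root" & fx$z >= zmax - apical_cap_mm] <- "apical"
  zone[zone == "mid_root" & fx$z <= zmin + cervical_fraction * h] <- "cervical"
  zones <- c("cervical", "mid_root", "apical", "furcation_roof")
  total_axial <- sum(fx$tz * fx$area)
  rows <- lapply(zones, function(zn) {
    i <- zone == zn
    if (!any(i))
      return(data.frame(zone = zn, area_mm2 = 0, peak_MPa = NA_real_,
                        mean_MPa = NA_real_, axial_share = 0))
    data.frame(zone = zn, area_mm2 = sum(fx$area[i]),
               peak_MPa = max(fx$pressure[i]),
               mean_MPa = sum(fx$pressure[i] * fx$area[i]) / sum(fx$area[i]),
               axial_share = if (abs(total_axial) > 0)
                 sum(fx$tz[i] * fx$area[i]) / total_axial else NA_real_)
  })
  out <- do.call(rbind, rows)
  structure(out, class = c("regional_summary", "data.frame"),
            interface_height = h, reduction = model$attachment_reduction)
}

#' Zone value accessor
#' @param summary a `regional_summary`.
#' @param zone zone name.
#' @param what column name (default `"peak_MPa"`).
#' @return scalar value.
#' @export
zone_value <- function(summary, zone, what = "peak_MPa") {
  summary[[what]][match(zone, summary$zone)]
}

#' Failure detection over an attachment-loss history
#'
#' A tooth is predicted to fail when the peak PDL contact pressure exceeds
#' a threshold (0.90 MPa by default) or when a reduction step leaves the
#' model unsupported / the solve fails.
#'
#' @param history data.frame with columns `reduction`, `peak_MPa` and
#'   optionally `solver_ok` (logical), or a numeric vector of peak
#'   pressures (reductions then taken as `0, 1, 2, ...`).
#' @param threshold_MPa failure threshold on the peak pressure.
#' @return object of class `failure_verdict`: list with `failed`,
#'   `criterion` (`"pressure_threshold"` or `"solver_failure"`),
#'   `threshold_MPa` and `triggering_reduction` (mm, `NA` if not failed).
#' @export
detect_failure <- function(history, threshold_MPa = 0.90) {
  if (is.numeric(history))
    history <- data.frame(reduction = seq_along(history) - 1,
                          peak_MPa = history)
  if (is.null(history$solver_ok)) history$solver_ok <- TRUE
  verdict <- list(failed = FALSE, criterion = NA_character_,
                  threshold_MPa = threshold_MPa,
                  triggering_reduction = NA_real_)
  for (i in seq_len(nrow(history))) {
    if (!isTRUE(history$solver_ok[i])) {
      verdict$failed <- TRUE
      verdict$criterion <- "solver_failure"
      verdict$triggering_reduction <- history$reduction[i]
      break
    }
    if (!is.na(history$peak_MPa[i]) && history$peak_MPa[i] > threshold_MPa) {
      verdict$failed <- TRUE
      verdict$criterion <- "pressure_threshold"
      verdict$triggering_reduction <- history$reduction[i]
      break
    }
  }
  structure(verdict, class = "failure_verdict")
}

#' @export
print.failure_verdict <- function(x, ...) {
  if (x$failed)
    cat(sprintf("<failure_verdict> FAILED at %g mm reduction (%s, threshold %g MPa)\n",
                x$triggering_reduction, x$criterion, x$threshold_MPa))
  else
    cat(sprintf("<failure_verdict> no failure (threshold %g MPa)\n",
                x$threshold_MPa))
  invisible(x)
}

#' Export solution fields to VTU / CSV / PNG
#'
#' @param solution a `solution_field`.
#' @param mesh its mesh (defaults to `solution$mesh`).
#' @param pressure optional `contact_pressure_map` to export alongside.
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @param formats subset of `c("vtu", "csv", "png")`.
#' @param model optional `tooth_model` for the regional CSV.
#' @return named character vector of written files, invisibly.
#' @export
export_fields <- function(solution, mesh = solution$mesh, pressure = NULL,
                          dir = ".", prefix = "field",
                          formats = c("vtu", "csv", "png"), model = NULL) {
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok || !dir.exists(dir)) stop("cannot create output directory: ", dir)
  }
  out <- character(0)
  inv <- stress_invariants(solution)
  if ("vtu" %in% formats) {
    path <- file.path(dir, paste0(prefix, ".vtu"))
    write_vtu(mesh, path,
              point_data = list(displacement = matrix(solution$u, ncol = 3,
                                                      byrow = TRUE)),
              cell_data = list(region = mesh$region,
                               von_mises = inv$von_mises,
                               s1 = inv$s1, s3 = inv$s3))
    out["vtu"] <- path
  }
  if (!is.null(pressure) && "csv" %in% formats) {
    path <- file.path(dir, paste0(prefix, "_pressure.csv"))
    write.csv(pressure$facets, path, row.names = FALSE)
    out["pressure_csv"] <- path
    if (!is.null(model)) {
      rs <- regional_summary(pressure, model)
      path2 <- file.path(dir, paste0(prefix, "_zones.csv"))
      write.csv(as.data.frame(rs), path2, row.names = FALSE)
      out["zones_csv"] <- path2
    }
  }
  if (!is.null(pressure) && "png" %in% formats) {
    path <- file.path(dir, paste0(prefix, "_pressure.png"))
    png(path, width = 900, height = 700)
    fx <- pressure$facets
    pal <- colorRampPalette(c("navy", "white", "red"))(256)
    pr <- fx$pressure
    col <- pal[pmin(256, pmax(1, findInterval(pr, seq(min(pr), max(pr),
                                                      length.out = 256))))]
    theta <- atan2(fx$y, fx$x)
    plot(theta, -fx$z, col = col, pch = 16, cex = 0.7,
         xlab = "angle around root axis (rad)", ylab = "-z (mm, apex down)",
         main = sprintf("PDL-bone contact pressure (peak %.3f MPa)",
                        pressure$peak))
    dev.off()
    out["png"] <- path
  }
  invisible(out)
}
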