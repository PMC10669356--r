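# Study orchestration: load calibration, the attachment-loss sweep, and the
# comparison between single- and multi-rooted tooth classes.

#' Calibrate the load protocol against a pressure anchor
#'
#' Scales the protocol (both force components, preserving their ratio) so
#' that the full-support model's peak PDL contact pressure equals a given
#' anchor.  Because the model is linear the scaling is exact.  Calibration
#' makes attachment-loss trends comparable across geometries without
#' assuming a particular muscle-to-tooth force transmission.
#'
#' @param model a full-support `tooth_model`.
#' @param protocol starting [load_protocol()].
#' @param anchor_MPa target peak PDL pressure at full support.
#' @param size,order meshing controls.
#' @return the scaled protocol, with attributes `calibration_factor` and
#'   `anchor_MPa`.
#' @export
calibrate_load <- function(model, protocol = load_protocol(),
                           anchor_MPa = 0.48, size = 1.2, order = 2L) {
  if (model$attachment_reduction != 0)
    stop("calibration requires the full-support model (reduction 0)")
  sol <- solve_static(model, protocol = protocol, size = size, order = order)
  pm <- contact_pressure(sol)
  factor <- anchor_MPa / pm$peak
  out <- scale_protocol(protocol, factor)
  attr(out, "calibration_factor") <- factor
  attr(out, "anchor_MPa") <- anchor_MPa
  out
}

#' Attachment-loss sweep
#'
#' Rebuilds, meshes and solves the model at a sequence of attachment
#' reductions (1 mm steps by default), recording the peak PDL contact
#' pressure, zone summaries and a failure verdict.  After the first
#' confirmed failure one further reduction is evaluated for confirmation
#' and the remaining steps are reported as not evaluated.
#'
#' @param tooth a [tooth_params()] object (or `tooth_model`).
#' @param protocol a [load_protocol()]; when `calibrate_to` is given the
#'   protocol is first calibrated on the full-support model.
#' @param reductions increasing attachment reductions in mm, starting at 0.
#' @param size,order meshing controls.
#' @param calibrate_to optional peak-pressure anchor (MPa) for
#'   [calibrate_load()].
#' @param failure_threshold_MPa failure threshold for [detect_failure()].
#' @param stop_after_failure evaluate one confirmation step after the first
#'   failure, then stop.
#' @param verbose print progress.
#' @return object of class `sweep_result`: `rows` (one per reduction),
#'   `zones` (list of [regional_summary()]), `verdict`, `metadata`.
#' @export
run_sweep <- function(tooth, protocol = load_protocol(), reductions = 0:9,
                      size = 2.0, order = 2L, calibrate_to = NULL,
                      failure_threshold_MPa = 0.90,
                      stop_after_failure = TRUE, verbose = FALSE) {
  model <- if (inherits(tooth, "tooth_model")) tooth else build_tooth(tooth)
  if (is.unsorted(reductions, strictly = TRUE) || any(reductions < 0))
    stop("reductions must be strictly increasing and non-negative")
  if (any(reductions > model$params$root_length))
    stop("reductions exceed root_length")
  calibration_factor <- NA_real_
  if (!is.null(calibrate_to)) {
    protocol <- calibrate_load(model, protocol, anchor_MPa = calibrate_to,
                               size = size, order = order)
    calibration_factor <- attr(protocol, "calibration_factor")
  }
  nr <- length(reductions)
  rows <- data.frame(reduction = reductions,
                     applied_N = resultant_force(protocol),
                     peak_MPa = NA_real_, p99_MPa = NA_real_,
                     mean_MPa = NA_real_, interface_area_mm2 = NA_real_,
                     equilibrium_gap = NA_real_,
                     reaction_residual = NA_real_,
                     linearity_residual = NA_real_,
                     apical_share = NA_real_, cervical_peak_MPa = NA_real_,
                     mid_root_peak_MPa = NA_real_, apical_peak_MPa = NA_real_,
                     furcation_peak_MPa = NA_real_,
                     solver_ok = NA, evaluated = FALSE)
  zones <- vector("list", nr)
  mesh_cells <- NA_integer_
  failures <- 0L
  for (i in seq_len(nr)) {
    if (stop_after_failure && failures >= 2L) break
    red <- reductions[i]
    if (verbose) message(sprintf("  reduction %g mm ...", red))
    rows$evaluated[i] <- TRUE
    res <- tryCatch({
      m <- generate_mesh(reduce_attachment(model, red), size = size,
                         order = order)
      if (i == 1L) mesh_cells <- nrow(m$elems)
      sys <- assemble(m)
      sys <- apply_supports(sys, "outer_bone_boundary")
      sol <- run_load_protocol(sys, protocol, keep = "terminal")
      pm <- contact_pressure(sol, m)
      rs <- regional_summary(pm, m$model)
      list(pm = pm, rs = rs, checks = sol$checks)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      rows$solver_ok[i] <- FALSE
      failures <- failures + 1L
      if (verbose) message("    failed: ", conditionMessage(res))
      next
    }
    pm <- res$pm; rs <- res$rs
    rows$solver_ok[i] <- TRUE
    rows$peak_MPa[i] <- pm$peak
    rows$p99_MPa[i] <- pm$p99
    rows$mean_MPa[i] <- pm$mean
    rows$interface_area_mm2[i] <- pm$area
    rows$equilibrium_gap[i] <- pm$equilibrium_gap
    rows$reaction_residual[i] <- res$checks$equilibrium_rel
    rows$linearity_residual[i] <- res$checks$linearity_rel
    rows$apical_share[i] <- zone_value(rs, "apical", "axial_share")
    rows$cervical_peak_MPa[i] <- zone_value(rs, "cervical")
    rows$mid_root_peak_MPa[i] <- zone_value(rs, "mid_root")
    rows$apical_peak_MPa[i] <- zone_value(rs, "apical")
    rows$furcation_peak_MPa[i] <- zone_value(rs, "furcation_roof")
    zones[[i]] <- rs
    if (pm$peak > failure_threshold_MPa) failures <- failures + 1L
  }
  verdict <- detect_failure(rows[rows$evaluated, c("reduction", "peak_MPa",
                                                   "solver_ok")],
                            threshold_MPa = failure_threshold_MPa)
  ev <- which(rows$evaluated & isTRUE(rows$solver_ok) |
                (rows$evaluated & rows$solver_ok %in% TRUE))
  pk <- rows$peak_MPa[ev]
  if (length(pk) > 1 && any(diff(pk) < 0))
    warning("peak PDL pressure not monotone in reduction: check mesh convergence")
  metadata <- list(
    params = model$params, protocol = protocol,
    calibration_factor = calibration_factor,
    failure_threshold_MPa = failure_threshold_MPa,
    mesh_size = size, order = order, n_elements_baseline = mesh_cells,
    n_steps = protocol$n_steps,
    package_version = as.character(utils::packageVersion("periofem")),
    fingerprint = signif(sum(rows$peak_MPa, na.rm = TRUE), 12)
  )
  structure(list(rows = rows, zones = zones, verdict = verdict,
                 metadata = metadata),
            class = "sweep_result")
}

#' @export
print.sweep_result <- function(x, ...) {
  cat(sprintf("<sweep_result> %s, resultant load %.1f N\n",
              x$metadata$params$tooth_class, x$rows$applied_N[1]))
  print(x$rows[, c("reduction", "peak_MPa", "mean_MPa", "apical_share",
                   "solver_ok", "evaluated")], row.names = FALSE)
  print(x$verdict)
  invisible(x)
}

#' Compare single- and multi-rooted sweep results
#'
#' @param single,multi `sweep_result` objects computed under the same
#'   (shared) load calibration.
#' @return object of class `class_comparison`: per-class summary table
#'   (baseline peak, failure reduction, maximum supported reduction),
#'   normalized pressure curves, and the ordering flag
#'   `multi_ge_single` (multi-rooted failure reduction >= single-rooted).
#' @export
compare_tooth_classes <- function(single, multi) {
  stopifnot(inherits(single, "sweep_result"), inherits(multi, "sweep_result"))
  f1 <- terminal_force_vector(single$metadata$protocol)
  f2 <- terminal_force_vector(multi$metadata$protocol)
  if (max(abs(f1 - f2)) > 1e-9 * max(abs(f1), 1))
    stop("incompatible load calibrations: terminal forces differ")
  fail_red <- function(sw) {
    if (sw$verdict$failed) sw$verdict$triggering_reduction else Inf
  }
  max_supported <- function(sw) {
    r <- sw$rows
    ok <- r$evaluated & r$solver_ok %in% TRUE &
      (is.na(r$peak_MPa) | r$peak_MPa <= sw$verdict$threshold_MPa)
    if (!any(ok)) return(NA_real_)
    max(r$reduction[ok])
  }
  curve <- function(sw) {
    r <- sw$rows[sw$rows$evaluated & sw$rows$solver_ok %in% TRUE, ]
    data.frame(reduction = r$reduction,
               pressure_MPa = r$peak_MPa,
               normalized = r$peak_MPa / r$peak_MPa[1])
  }
  table <- data.frame(
    class = c(single$metadata$params$tooth_class,
              multi$metadata$params$tooth_class),
    baseline_peak_MPa = c(single$rows$peak_MPa[1], multi$rows$peak_MPa[1]),
    failure_reduction_mm = c(fail_red(single), fail_red(multi)),
    max_supported_mm = c(max_supported(single), max_supported(multi))
  )
  structure(list(table = table,
                 curves = list(single = curve(single), multi = curve(multi)),
                 multi_ge_single = fail_red(multi) >= fail_red(single)),
            class = "class_comparison")
}

#' @export
print.class_comparison <- function(x, ...) {
  print(x$table, row.names = FALSE)
  cat(sprintf("multi-rooted failure reduction >= single-rooted: %s\n",
              x$multi_ge_single))
  invisible(x)
}

#' Pressure-versus-force-and-reduction surface plots
#'
#' Renders the sweep as pressure against applied force (the linear ramp)
#' for each reduction, and as a force x reduction pressure surface; the
#' plotted numbers are also written to a CSV twin.
#'
#' @param result a `sweep_result` with at least two evaluated reductions.
#' @param dir output directory.
#' @param prefix file-name prefix.
#' @return character vector of written files (PNG lines, PNG surface, CSV).
#' @export
plot_pressure_surface <- function(result, dir = ".", prefix = "sweep") {
  stopifnot(inherits(result, "sweep_result"))
  r <- result$rows[result$rows$evaluated & result$rows$solver_ok %in% TRUE, ]
  if (nrow(r) < 2) stop("need at least two evaluated reductions to plot")
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  n_steps <- result$metadata$n_steps
  fr <- seq_len(n_steps) / n_steps
  FN <- resultant_force(result$metadata$protocol)
  # linear in force at fixed reduction: pressure(f, red) = f * peak(red)
  grid <- expand.grid(force_N = fr * FN, reduction_mm = r$reduction)
  grid$pressure_MPa <- rep(r$peak_MPa, each = n_steps) *
    rep(fr, times = nrow(r))
  csv <- file.path(dir, paste0(prefix, "_pressure_surface.csv"))
  write.csv(grid, csv, row.names = FALSE)

  p1 <- file.path(dir, paste0(prefix, "_pressure_vs_force.png"))
  png(p1, width = 900, height = 700)
  M <- outer(fr * FN, r$peak_MPa / FN)
  matplot(fr * FN, M, type = "l", lty = 1,
          xlab = "applied resultant force (N)",
          ylab = "peak PDL contact pressure (MPa)",
          main = "Pressure vs force, by attachment reduction")
  legend("topleft", legend = sprintf("%g mm", r$reduction), lty = 1,
         col = seq_len(nrow(r)), cex = 0.8, title = "reduction")
  dev.off()

  p2 <- file.path(dir, paste0(prefix, "_pressure_surface.png"))
  png(p2, width = 900, height = 700)
  image(x = fr * FN, y = r$reduction, z = M,
        xlab = "applied resultant force (N)", ylab = "attachment reduction (mm)",
        main = "Peak PDL pressure (MPa)", col = grDevices::hcl.colors(64, "YlOrRd",
                                                                      rev = TRUE))
  dev.off()
  c(lines = p1, surface = p2, csv = csv)
}
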