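# YAML run configuration and the programmatic entry point used by the
# command-line wrapper.

#' Read a YAML run configuration
#'
#' Recognized blocks: `tooth:` ([tooth_params()] keys), `reduction_mm:`
#' (scalar or list), `load:` (`n_steps`, `axial_N`, `transverse_N`,
#' `calibrate_to_MPa`), `mesh:` (`size`, `order`), `support:` (facet-set
#' name), `materials:` (per-tissue `elastic_modulus` / `poisson_ratio`
#' overrides), `failure_threshold_MPa:`, `out:` (output directory).
#'
#' @param path YAML file.
#' @return validated configuration list of class `run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  known <- c("tooth", "reduction_mm", "load", "mesh", "support", "materials",
             "failure_threshold_MPa", "out")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown))
    stop("unknown config block(s): ", paste(unknown, collapse = ", "))
  cfg$tooth <- do.call(tooth_params, cfg$tooth %||% list())
  load <- cfg$load %||% list()
  cfg$protocol <- load_protocol(
    n_steps = load$n_steps %||% 70L,
    axial_N = load$axial_N %||% 70,
    transverse_N = load$transverse_N %||% 35)
  cfg$calibrate_to <- load$calibrate_to_MPa
  mesh <- cfg$mesh %||% list()
  cfg$mesh_size <- mesh$size %||% 1.5
  cfg$order <- mesh$order %||% 2L
  cfg$support <- cfg$support %||% "outer_bone_boundary"
  cfg$reduction_mm <- cfg$reduction_mm %||% 0
  cfg$failure_threshold_MPa <- cfg$failure_threshold_MPa %||% 0.90
  if (!is.null(cfg$materials)) {
    cfg$material_overrides <- lapply(cfg$materials, function(m)
      list(elastic_modulus = m$elastic_modulus, poisson_ratio = m$poisson_ratio))
  }
  class(cfg) <- "run_config"
  cfg
}

#' Run a solve or sweep from a configuration
#'
#' A single `reduction_mm` value runs one static solve and exports the
#' fields; a vector runs [run_sweep()] and writes the result table, its
#' JSON twin with metadata, and the pressure plots.
#'
#' @param config path to a YAML file or a `run_config` list.
#' @param out output directory (overrides the config's `out:`).
#' @return the `solution_field` or `sweep_result`, invisibly.
#' @export
run_from_config <- function(config, out = NULL) {
  cfg <- if (inherits(config, "run_config")) config else read_run_config(config)
  out <- out %||% cfg$out %||% "periofem_out"
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  model <- build_tooth(cfg$tooth)
  materials <- if (!is.null(cfg$material_overrides))
    materials_for(REGIONS, overrides = cfg$material_overrides) else NULL
  if (length(cfg$reduction_mm) > 1) {
    res <- run_sweep(model, protocol = cfg$protocol,
                     reductions = sort(unlist(cfg$reduction_mm)),
                     size = cfg$mesh_size, order = cfg$order,
                     calibrate_to = cfg$calibrate_to,
                     failure_threshold_MPa = cfg$failure_threshold_MPa)
    write.csv(res$rows, file.path(out, "results.csv"), row.names = FALSE)
    jsonlite::write_json(
      list(rows = res$rows,
           verdict = unclass(res$verdict),
           metadata = list(
             tooth = unclass(res$metadata$params),
             protocol = unclass(res$metadata$protocol),
             calibration_factor = res$metadata$calibration_factor,
             mesh_size = res$metadata$mesh_size,
             order = res$metadata$order,
             n_elements_baseline = res$metadata$n_elements_baseline,
             package_version = res$metadata$package_version)),
      file.path(out, "results.json"), auto_unbox = TRUE, digits = NA,
      pretty = TRUE)
    try(plot_pressure_surface(res, dir = out), silent = TRUE)
  } else {
    model <- reduce_attachment(model, cfg$reduction_mm)
    mesh <- generate_mesh(model, size = cfg$mesh_size, order = cfg$order)
    sys <- assemble(mesh, materials)
    sys <- apply_supports(sys, cfg$support)
    res <- run_load_protocol(sys, cfg$protocol, keep = "terminal")
    pm <- contact_pressure(res, mesh)
    export_fields(res, mesh, pressure = pm, dir = out, prefix = "solution",
                  model = model)
  }
  invisible(res)
}
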