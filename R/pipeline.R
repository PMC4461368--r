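#' Pipeline configuration
#'
#' Collects every tunable parameter of the analysis with defaults equal to
#' the field-standard values used throughout the package: 1-degree histogram
#' bins, 60-degree minima merging, 5-degree fixed transition-state arcs,
#' 6.5 Angstrom CA contact cutoff with 2/3 reference prevalence, 3.5
#' Angstrom / 130 degree hydrogen-bond rule, and a 1.4 Angstrom probe
#' radius.
#'
#' @param input Path to an angle table (see [read_angle_table()]), or `NULL`
#'   when `simulate` is given.
#' @param simulate An [ensemble_spec()] to generate input synthetically.
#' @param mode `"backbone"` (two-state DOFs) or `"sidechain"` (admits
#'   three-state DOFs).
#' @param smoothing_window,merge_distance,keep Passed to
#'   [fit_torsion_states()].
#' @param tse_ratio_threshold Passed to [derive_tse_regions()].
#' @param probe_radius SASA probe radius (Angstrom).
#' @param seed Integer seed for all stochastic stages.
#' @param out_dir Output directory for TSV/GraphML artifacts, or `NULL` to
#'   skip writing.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(input = NULL, simulate = NULL,
                            mode = c("backbone", "sidechain"),
                            smoothing_window = 5, merge_distance = 60,
                            keep = "deeper", tse_ratio_threshold = 3,
                            probe_radius = 1.4, seed = 1L, out_dir = NULL) {
  mode <- match.arg(mode)
  if (is.null(input) && is.null(simulate)) {
    stop("either an input angle table or a simulation spec is required")
  }
  if (!is.null(input) && !file.exists(input)) {
    stop("input path does not exist: ", input)
  }
  structure(list(input = input, simulate = simulate, mode = mode,
                 smoothing_window = smoothing_window,
                 merge_distance = merge_distance, keep = keep,
                 tse_ratio_threshold = tse_ratio_threshold,
                 probe_radius = probe_radius, seed = as.integer(seed),
                 out_dir = out_dir),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Top-level keys mirror the arguments of [pipeline_config()]; a `simulate`
#' block holds `n_trajectories`, `frames_per_trajectory`,
#' `frame_interval_ps` and a `dofs` list of telegraph parameters.
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  sim <- NULL
  if (!is.null(y$simulate)) {
    dofs <- lapply(y$simulate$dofs, function(d) {
      do.call(telegraph_spec, d)
    })
    sim <- ensemble_spec(y$simulate$n_trajectories,
                         y$simulate$frames_per_trajectory,
                         y$simulate$frame_interval_ps, dofs,
                         seed = y$seed %||% 1L)
  }
  args <- y[setdiff(names(y), "simulate")]
  do.call(pipeline_config, c(args, list(simulate = sim)))
}

#' Run the full torsional conformational-analysis pipeline
#'
#' Executes simulate/read, state detection, timescale stratification,
#' hierarchical clustering at every populated band, transition networks,
#' transition-state-ensemble labeling and lifetimes, and dihedral PCA. A
#' rerun with the same configuration and seed is bit-identical for the
#' deterministic stages.
#'
#' @param config A `pipeline_config` (or the path of a YAML file).
#' @return A list of class `pipeline_result`: `ensemble`, `fit`,
#'   `timescales`, `clustering_dofs`, `hierarchy`, `networks` (per band),
#'   `tse_regions`, `tse_events` (finest band), `lifetimes`, `dpca`,
#'   `metadata`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  ensemble <- stage("input", {
    if (!is.null(config$simulate)) simulate_ensemble(config$simulate)
    else read_angle_table(config$input)
  })
  fit <- stage("states", fit_torsion_states(
    ensemble, smoothing_window = config$smoothing_window,
    merge_distance = config$merge_distance, keep = config$keep))
  states <- stage("states", assign_states(ensemble, fit))
  dofs <- stage("states", select_clustering_dofs(fit, mode = config$mode))
  if (length(dofs) == 0) stop("pipeline stage 'states' failed: no ",
                              "multi-state DOFs eligible for clustering",
                              call. = FALSE)
  ts <- stage("timescales", dof_timescales(states, dofs = dofs))
  ns <- vapply(fit$models, `[[`, integer(1), "n_states")
  hier <- stage("cluster", cluster_hierarchy(states, ts,
                                             n_states_per_dof = ns))
  nets <- stage("network", {
    ns_list <- lapply(hier$resolutions, function(r) build_network(hier, r))
    stats::setNames(ns_list, hier$resolutions)
  })
  regions <- stage("tse", derive_tse_regions(
    ensemble, fit, ts, ratio_threshold = config$tse_ratio_threshold))
  finest <- hier$resolutions[length(hier$resolutions)]
  events <- stage("tse", label_tse_events(ensemble, regions, hier, finest))
  lifetimes <- stage("tse", if (nrow(events) > 0) {
    lifetime_stats(events, by = "band", timescales = ts)
  } else NULL)
  pca <- stage("dpca", fit_dpca(ensemble))
  metadata <- list(seed = config$seed, mode = config$mode,
                   config_hash = config_hash(config),
                   n_frames = hier$n_frames,
                   version = as.character(utils::packageVersion("torsionfel")))
  res <- structure(list(ensemble = ensemble, fit = fit, timescales = ts,
                        clustering_dofs = dofs, hierarchy = hier,
                        networks = nets, tse_regions = regions,
                        tse_events = events, lifetimes = lifetimes,
                        dpca = pca, metadata = metadata),
                   class = "pipeline_result")
  if (!is.null(config$out_dir)) write_pipeline_outputs(res, config$out_dir)
  res
}

config_hash <- function(config) {
  s <- paste(utils::capture.output(utils::str(unclass(config))),
             collapse = "\n")
  # small deterministic FNV-1a style hash; avoids a digest dependency
  h <- 2166136261
  for (ch in utf8ToInt(s)) h <- bitwXor(h, ch) * 16777619 %% 2^32
  sprintf("%08x", h %% 2^31)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result> ", x$metadata$n_frames, " frames, ",
      length(x$clustering_dofs), " clustering DOFs\n", sep = "")
  print(glance(x$hierarchy))
  invisible(x)
}

write_pipeline_outputs <- function(res, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  meta <- sprintf("# %s\t%s", names(res$metadata),
                  vapply(res$metadata, as.character, character(1)))
  tsv <- function(df, name) {
    p <- file.path(dir, name)
    writeLines(meta, p)
    suppressWarnings(utils::write.table(df, p, sep = "\t", quote = FALSE,
                                        row.names = FALSE, append = TRUE))
  }
  tsv(dplyr::mutate(res$timescales), "timescales.tsv")
  write_state_models(res$fit, file.path(dir, "state_models.tsv"))
  write_cluster_tables(res$hierarchy, dir)
  for (r in names(res$networks)) {
    tsv(tidy(res$networks[[r]]), paste0("edges_", r, ".tsv"))
    write_network_graphml(res$networks[[r]],
                          file.path(dir, paste0("network_", r, ".graphml")))
  }
  tsv(res$tse_regions, "tse_regions.tsv")
  tsv(res$tse_events, "tse_events.tsv")
  if (!is.null(res$lifetimes)) tsv(res$lifetimes, "tse_lifetimes.tsv")
  tsv(tidy(res$dpca), "dpca_eigenvalues.tsv")
  invisible(dir)
}
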