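#' Default pipeline configuration
#'
#' Nested configuration shared by all command-line subcommands and by
#' [run_scenario_grid()].  Sections: `population` (panel simulation),
#' `filter` (marker filtering), `phenotype` (causal selection and trait
#' simulation), `weighting` (sample prioritization), `models` (rf/gbm
#' hyperparameters and iteration count), `grid` (scenario sweep), and a
#' top-level `seed`.
#'
#' @return A nested list of defaults.
#' @export
default_config <- function() {
  list(
    seed = 1L,
    population = list(n_wild = 143L, n_hybrid = 140L, n_markers = 1946L,
                      ld_block_size = 4L, wild_maf_range = c(0.1, 0.5),
                      shared_marker_fraction = 0.8, n_parents = 20L,
                      recomb_rate = 0.02, ld_rho = 0.98),
    filter = list(threshold = 0.7, signed = FALSE),
    phenotype = list(target_ve = 0.4, effect = 1,
                     maf_ratio_threshold = 1.5, suppression = TRUE,
                     suppression_factor = 1),
    weighting = list(top_marker_cutoff = 10L, wild_seg_quantile = 0.10,
                     hybrid_seg_quantile = 0.10, metric = "gower",
                     tail_mode = "both", exclude_unfiltered = FALSE),
    models = list(n_trees = 1000L, eta = 0.3, n_rounds = 100L,
                  max_depth = 6L, n_iter = 100L),
    grid = list(effect_sizes = c(0.4, 0.8),
                models = c("rf", "gbm", "rf_weighted", "gbm_weighted",
                           "regression"),
                metrics = c("gower", "jaccard"),
                top_marker_cutoffs = c(5, 10, 15, 20),
                wild_seg_quantiles = c(0.05, 0.10, 0.15, 0.20, 0.25),
                hybrid_seg_quantiles = c(0.05, 0.10, 0.15, 0.20, 0.25),
                n_replicates = 100L)
  )
}

#' Load and validate a YAML configuration
#'
#' Reads a YAML file, merges it over [default_config()] and validates it.
#' Unknown keys (top-level or within a section) are rejected by name; an
#' empty file yields the all-defaults configuration.
#'
#' @param path path to a YAML file.
#' @return The validated configuration list.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop_cfg("config file not found: ", path)
  user <- yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  validate_config(user)
}

#' @rdname load_config
#' @param user a (possibly partial) configuration list to merge over the
#'   defaults.
#' @export
validate_config <- function(user = list()) {
  cfg <- default_config()
  unknown <- setdiff(names(user), names(cfg))
  if (length(unknown))
    stop_cfg("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  for (sec in names(user)) {
    if (sec == "seed") { cfg$seed <- as.integer(user$seed); next }
    bad <- setdiff(names(user[[sec]]), names(cfg[[sec]]))
    if (length(bad))
      stop_cfg("unknown key(s) in section '", sec, "': ",
               paste(bad, collapse = ", "))
    cfg[[sec]][names(user[[sec]])] <- user[[sec]]
  }
  # touch every constructor so domain violations surface with the key name
  do.call(sim_pop_config, cfg$population)
  do.call(weighting_config, cfg$weighting)
  rf_config(n_trees = cfg$models$n_trees)
  gbm_config(eta = cfg$models$eta, n_rounds = cfg$models$n_rounds,
             max_depth = cfg$models$max_depth)
  with(cfg$grid, scenario_grid(effect_sizes = effect_sizes, models = models,
                               metrics = metrics,
                               top_marker_cutoffs = top_marker_cutoffs,
                               wild_seg_quantiles = wild_seg_quantiles,
                               hybrid_seg_quantiles = hybrid_seg_quantiles))
  if (cfg$phenotype$target_ve <= 0 || cfg$phenotype$target_ve > 1)
    stop_cfg("phenotype$target_ve must be in (0, 1]")
  if (cfg$filter$threshold <= 0 || cfg$filter$threshold >= 1)
    stop_cfg("filter$threshold must be in (0, 1)")
  cfg
}

#' Run manifest
#'
#' Snapshot sufficient to reproduce a run: the resolved configuration, the
#' seeds used per stage (derived from the master seed by the counter-based
#' splitting rule in [derive_seeds()]), package version, md5 digests of the
#' input files, and a timestamp.
#'
#' @param config resolved configuration list.
#' @param seeds named list of per-stage seeds.
#' @param inputs character vector of input file paths (digested with md5).
#' @return A `run_manifest` list.
#' @export
run_manifest <- function(config, seeds = list(), inputs = character(0)) {
  digests <- if (length(inputs)) as.list(tools::md5sum(inputs)) else list()
  structure(list(
    package = "transqtl",
    version = as.character(utils::packageVersion("transqtl")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed_rule = "stage seeds are successive draws of sample.int(2^31-2) under set.seed(master_seed + stream)",
    config = config, seeds = seeds, input_digests = digests),
    class = "run_manifest")
}

#' @rdname run_manifest
#' @param manifest a `run_manifest`.
#' @param path output JSON path.
#' @export
write_manifest <- function(manifest, path) {
  jsonlite::write_json(unclass(manifest), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}
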