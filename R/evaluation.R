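#' Detection rates across rank bins
#'
#' Fraction of simulation replicates in which the causal marker's average
#' importance rank fell strictly below each bin edge; the first default bin
#' ("rank < 2") counts replicates where the causal marker was the top
#' marker.  Bins are cumulative, so rates are non-decreasing across
#' widening edges.
#'
#' @param causal_ranks numeric vector of per-replicate causal-marker average
#'   ranks (all >= 1).
#' @param bin_edges numeric bin edges (default `c(2, 3, 4, 5, 6)`).
#' @return Named numeric vector of fractions in `[0, 1]`.
#' @export
detection_rates <- function(causal_ranks, bin_edges = c(2, 3, 4, 5, 6)) {
  causal_ranks <- causal_ranks[!is.na(causal_ranks)]
  if (length(causal_ranks) == 0L) stop_cfg("empty causal rank list")
  if (any(causal_ranks < 1)) stop_cfg("ranks must be >= 1")
  stats::setNames(vapply(bin_edges, function(e) mean(causal_ranks < e),
                         numeric(1)),
                  paste0("rank<", bin_edges))
}

#' Quantiles of the causal-rank distribution
#'
#' Empirical quantiles (linear-interpolation definition, R type 7) of the
#' causal marker's average ranks over replicates — the cumulative-curve
#' summary: "the 80% quantile coincides with marker rank r" means 80% of
#' replicates ranked the causal marker at or below r.
#'
#' @param causal_ranks numeric vector of causal-marker average ranks.
#' @param probs probabilities in (0, 1) (default `c(0.8, 0.9)`).
#' @return Named numeric vector of rank values.
#' @export
cumulative_rank_quantiles <- function(causal_ranks, probs = c(0.8, 0.9)) {
  causal_ranks <- causal_ranks[!is.na(causal_ranks)]
  if (length(causal_ranks) == 0L) stop_cfg("empty causal rank list")
  if (any(probs <= 0 | probs >= 1)) stop_cfg("probs must be in (0, 1)")
  stats::quantile(causal_ranks, probs = probs, type = 7)
}

#' Parameter grid for simulation scenarios
#'
#' @param effect_sizes target variance-explained values (the study uses 0.4
#'   and 0.8).
#' @param models model labels among `"rf"`, `"gbm"`, `"rf_weighted"`,
#'   `"gbm_weighted"`, `"regression"`.
#' @param metrics distance metrics for the weighted models.
#' @param top_marker_cutoffs focus-marker counts (study sweep: 5, 10, 15,
#'   20).
#' @param wild_seg_quantiles,hybrid_seg_quantiles segregation quantiles
#'   (study sweep: 0.05 to 0.25).
#' @param suppression apply trans-suppression to the hybrid phenotype.
#' @param suppression_factor attenuation factor in `[0, 1]` (1 = complete).
#' @return A `scenario_grid` list.
#' @export
scenario_grid <- function(effect_sizes = c(0.4, 0.8),
                          models = c("rf", "gbm", "rf_weighted",
                                     "gbm_weighted", "regression"),
                          metrics = c("gower", "jaccard"),
                          top_marker_cutoffs = c(5, 10, 15, 20),
                          wild_seg_quantiles = c(0.05, 0.10, 0.15, 0.20, 0.25),
                          hybrid_seg_quantiles = c(0.05, 0.10, 0.15, 0.20, 0.25),
                          suppression = TRUE, suppression_factor = 1) {
  models <- match.arg(models, several.ok = TRUE)
  metrics <- match.arg(metrics, several.ok = TRUE)
  if (any(effect_sizes <= 0 | effect_sizes > 1))
    stop_cfg("effect sizes (variance explained) must be in (0, 1]")
  if (any(c(wild_seg_quantiles, hybrid_seg_quantiles) <= 0) ||
      any(c(wild_seg_quantiles, hybrid_seg_quantiles) >= 0.5))
    stop_cfg("segregation quantiles must be in (0, 0.5)")
  structure(list(effect_sizes = effect_sizes, models = models,
                 metrics = metrics, top_marker_cutoffs = top_marker_cutoffs,
                 wild_seg_quantiles = wild_seg_quantiles,
                 hybrid_seg_quantiles = hybrid_seg_quantiles,
                 suppression = suppression,
                 suppression_factor = suppression_factor),
            class = "scenario_grid")
}

#' Run the simulation scenario grid
#'
#' For each replicate: simulate a wild panel and an F2 hybrid panel, select
#' a causal marker (wild/hybrid MAF ratio filter) and an unlinked
#' suppressor, simulate phenotypes in both populations at each effect size
#' (suppressing the hybrid genetic signal when requested), reduce the
#' hybrid panel to independent markers by correlation-graph filtering (the
#' causal marker represents its own component), then record the causal
#' marker's average importance rank under every model in the grid.
#' Everything is deterministic given `master_seed`; per-replicate and
#' per-stage seeds are derived by a counter-based splitting rule.
#'
#' @param grid a [scenario_grid].
#' @param sim_config a [sim_pop_config] describing the panels (its `seed` is
#'   ignored; seeds come from `master_seed`).
#' @param n_replicates replicates per grid cell (default 100).
#' @param n_iter model iterations per rank table (default 100).
#' @param master_seed integer master seed.
#' @param corr_threshold marker-filter correlation cutoff (default 0.7).
#' @param maf_ratio_threshold causal-marker MAF ratio cutoff (default 1.5).
#' @param rf,gbm model configurations.
#' @param verbose print per-replicate progress.
#' @return A `scenario_result`: list with `results` (long data frame of
#'   causal ranks), `failures`, and the run settings.
#' @export
run_scenario_grid <- function(grid = scenario_grid(),
                              sim_config = sim_pop_config(),
                              n_replicates = 100, n_iter = 100,
                              master_seed = 1,
                              corr_threshold = 0.7,
                              maf_ratio_threshold = 1.5,
                              rf = rf_config(), gbm = gbm_config(),
                              verbose = FALSE) {
  if (!inherits(grid, "scenario_grid")) stop_cfg("'grid' must be a scenario_grid")
  rep_seeds <- derive_seeds(master_seed, n_replicates)
  rows <- list()
  failures <- character(0)
  weighted_models <- intersect(grid$models, c("rf_weighted", "gbm_weighted"))
  plain_models <- setdiff(grid$models, weighted_models)
  wcells <- if (length(weighted_models))
    expand.grid(metric = grid$metrics, cutoff = grid$top_marker_cutoffs,
                wild_q = grid$wild_seg_quantiles,
                hybrid_q = grid$hybrid_seg_quantiles,
                stringsAsFactors = FALSE)
  else NULL
  for (rep in seq_len(n_replicates)) {
    res <- tryCatch(
      run_one_replicate(rep, rep_seeds[[rep]], grid, sim_config, n_iter,
                        corr_threshold, maf_ratio_threshold, rf, gbm,
                        plain_models, weighted_models, wcells),
      error = function(e) conditionMessage(e))
    if (is.character(res)) {
      failures <- c(failures, sprintf("replicate %d: %s", rep, res))
      warning("replicate ", rep, " failed: ", res, call. = FALSE)
    } else {
      rows[[length(rows) + 1L]] <- res
    }
    if (verbose) message("replicate ", rep, "/", n_replicates, " done")
  }
  results <- do.call(rbind, rows)
  if (length(failures) > 0.1 * n_replicates)
    warning("more than 10% of replicates failed", call. = FALSE)
  structure(list(results = results, failures = failures, grid = grid,
                 sim_config = sim_config, n_replicates = n_replicates,
                 n_iter = n_iter, master_seed = master_seed),
            class = "scenario_result")
}

run_one_replicate <- function(rep, rep_seed, grid, sim_config, n_iter,
                              corr_threshold, maf_ratio_threshold, rf, gbm,
                              plain_models, weighted_models, wcells) {
  pool <- derive_seeds(rep_seed, 64L + 4L * length(grid$effect_sizes) *
                         (1L + if (is.null(wcells)) 0L else nrow(wcells)))
  k <- 0L
  next_seed <- function() {
    k <<- k + 1L
    pool[[k]]
  }
  cfg_w <- sim_config; cfg_w$seed <- next_seed()
  wild <- simulate_wild_population(cfg_w)
  cfg_h <- sim_config; cfg_h$seed <- next_seed()
  hybrid <- simulate_f2_population(wild, cfg_h)
  causal <- select_causal_marker(wild, hybrid, maf_ratio_threshold,
                                 seed = next_seed())
  filt <- filter_markers(hybrid, threshold = corr_threshold,
                         causal_ids = causal, seed = next_seed())
  suppressor <- select_suppressor(hybrid, causal, filt$partition,
                                  seed = next_seed())
  rows <- list()
  for (ve in grid$effect_sizes) {
    hyb_pheno <- simulate_phenotype(hybrid, causal, ve, seed = next_seed())
    if (grid$suppression)
      hyb_pheno <- apply_trans_suppression(hyb_pheno, hybrid, suppressor,
                                           factor = grid$suppression_factor)
    wild_pheno <- simulate_phenotype(wild, causal, ve, seed = next_seed())
    for (mod in plain_models) {
      rt <- rank_markers(filt$genotypes, hyb_pheno, model = mod,
                         n_iter = n_iter,
                         config = if (mod == "rf") rf else
                           if (mod == "gbm") gbm else NULL,
                         seed = next_seed())
      rows[[length(rows) + 1L]] <- data.frame(
        replicate = rep, effect_size = ve, model_label = mod,
        metric = NA_character_, cutoff = NA_real_, wild_q = NA_real_,
        hybrid_q = NA_real_, causal_rank = marker_rank(rt, causal),
        stringsAsFactors = FALSE)
    }
    if (length(weighted_models)) {
      for (ci in seq_len(nrow(wcells))) {
        cell <- wcells[ci, ]
        wts <- prioritize_samples(
          hybrid, hyb_pheno, wild, wild_pheno,
          weighting_config(top_marker_cutoff = cell$cutoff,
                           wild_seg_quantile = cell$wild_q,
                           hybrid_seg_quantile = cell$hybrid_q,
                           metric = cell$metric))
        for (mod in weighted_models) {
          base <- sub("_weighted$", "", mod)
          rt <- rank_markers(filt$genotypes, hyb_pheno, model = base,
                             weights = wts, n_iter = n_iter,
                             config = if (base == "rf") rf else gbm,
                             seed = next_seed())
          rows[[length(rows) + 1L]] <- data.frame(
            replicate = rep, effect_size = ve, model_label = mod,
            metric = cell$metric, cutoff = cell$cutoff,
            wild_q = cell$wild_q, hybrid_q = cell$hybrid_q,
            causal_rank = marker_rank(rt, causal),
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  do.call(rbind, rows)
}

#' @export
print.scenario_result <- function(x, ...) {
  cat(sprintf("scenario_result: %d replicates, %d result rows, %d failure(s)\n",
              x$n_replicates,
              if (is.null(x$results)) 0L else nrow(x$results),
              length(x$failures)))
  s <- summary(x)
  print(utils::head(s, 12), row.names = FALSE)
  if (nrow(s) > 12) cat("  ...", nrow(s) - 12, "more cells\n")
  invisible(x)
}

#' Summarize scenario results as detection rates
#'
#' One row per grid cell (effect size x model x weighting parameters) with
#' the detection rate in each rank bin and the 80%/90% causal-rank
#' quantiles.
#'
#' @param object a `scenario_result`.
#' @param bin_edges rank-bin edges (default `c(2, 3, 4, 5, 6)`).
#' @param ... ignored.
#' @return A data frame.
#' @export
summary.scenario_result <- function(object, bin_edges = c(2, 3, 4, 5, 6),
                                    ...) {
  r <- object$results
  if (is.null(r) || nrow(r) == 0L) stop_cfg("no results to summarize")
  key_of <- function(v) ifelse(is.na(v), "", as.character(v))
  key <- paste(key_of(r$effect_size), key_of(r$model_label), key_of(r$metric),
               key_of(r$cutoff), key_of(r$wild_q), key_of(r$hybrid_q),
               sep = "|")
  cells <- split(r, key)
  out <- lapply(cells, function(cc) {
    dr <- detection_rates(cc$causal_rank, bin_edges)
    qq <- cumulative_rank_quantiles(cc$causal_rank)
    cbind(cc[1, c("effect_size", "model_label", "metric", "cutoff",
                  "wild_q", "hybrid_q")],
          n_replicates = nrow(cc),
          as.data.frame(as.list(dr), check.names = FALSE),
          q80 = unname(qq[1]), q90 = unname(qq[2]))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$effect_size, out$model_label), ]
}

#' Plot scenario detection rates
#'
#' Grouped bar chart of per-model detection rates across rank bins, one
#' panel per effect size.
#'
#' @param x a `scenario_result`.
#' @param bin_edges rank-bin edges.
#' @param ... passed to [graphics::barplot()].
#' @export
plot.scenario_result <- function(x, bin_edges = c(2, 3, 4, 5, 6), ...) {
  s <- summary(x, bin_edges = bin_edges)
  ves <- unique(s$effect_size)
  op <- graphics::par(mfrow = c(1, length(ves)))
  on.exit(graphics::par(op))
  bins <- paste0("rank<", bin_edges)
  for (ve in ves) {
    sv <- s[s$effect_size == ve, ]
    agg <- t(vapply(split(sv, sv$model_label),
                    function(cc) colMeans(cc[, bins, drop = FALSE]),
                    numeric(length(bins))))
    graphics::barplot(agg, beside = TRUE, ylim = c(0, 1),
                      legend.text = rownames(agg),
                      ylab = "detection rate",
                      main = sprintf("effect size %.1f", ve), ...)
  }
  invisible(x)
}

#' Write scenario results as long-format TSV
#'
#' @param x a `scenario_result`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_scenario_tsv <- function(x, path) {
  utils::write.table(summary(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
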