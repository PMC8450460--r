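#' Model configurations
#'
#' `rf_config()` parametrizes the random forest: 1000 regression trees with
#' RMSE loss and permutation-based out-of-bag variable importance.
#' `gbm_config()` parametrizes gradient boosting: squared-error loss with
#' learning rate `eta = 0.3` and gain-based variable importance; round count
#' and tree depth follow the common defaults of the gain-importance
#' ecosystem.
#'
#' @param n_trees number of trees in the forest (default 1000).
#' @param mtry variables tried per split; NULL uses the regression default
#'   (a third of the markers).
#' @return A config list.
#' @export
rf_config <- function(n_trees = 1000, mtry = NULL) {
  if (!is_count(n_trees)) stop_cfg("'n_trees' must be a positive integer")
  structure(list(n_trees = as.integer(n_trees), mtry = mtry,
                 loss = "rmse", importance = "permutation"),
            class = "rf_config")
}

#' @rdname rf_config
#' @param eta learning rate in (0, 1] (default 0.3).
#' @param n_rounds boosting rounds (default 100).
#' @param max_depth maximum tree depth (default 6).
#' @export
gbm_config <- function(eta = 0.3, n_rounds = 100, max_depth = 6) {
  if (!is.numeric(eta) || eta <= 0 || eta > 1)
    stop_cfg("'eta' must be in (0, 1]")
  if (!is_count(n_rounds)) stop_cfg("'n_rounds' must be a positive integer")
  if (!is_count(max_depth)) stop_cfg("'max_depth' must be a positive integer")
  structure(list(eta = eta, n_rounds = as.integer(n_rounds),
                 max_depth = as.integer(max_depth),
                 loss = "squarederror", importance = "gain"),
            class = "gbm_config")
}

as_train_matrix <- function(x) {
  X <- if (inherits(x, "geno_matrix")) x$dosage else x
  if (!is.matrix(X)) stop_cfg("training genotypes must be a matrix")
  if (ncol(X) < 2L) stop_cfg("need at least 2 markers")
  storage.mode(X) <- "double"
  X
}

#' Random forest permutation importance
#'
#' Fits a regression forest and returns, per marker, the mean increase in
#' out-of-bag prediction error after permuting that marker's dosages
#' (larger = more important).
#'
#' @param x training genotypes: a [geno_matrix] or dosage matrix.
#' @param y numeric phenotype vector.
#' @param cfg an [rf_config].
#' @param seed integer seed (forwarded to the forest) or NULL.
#' @return Named numeric importance scores, one per marker.
#' @export
fit_rf_importance <- function(x, y, cfg = rf_config(), seed = NULL) {
  X <- as_train_matrix(x)
  if (length(unique(y)) < 2L) stop_cfg("constant phenotype")
  fit <- ranger::ranger(x = X, y = as.numeric(y),
                        num.trees = cfg$n_trees,
                        mtry = cfg$mtry,
                        importance = "permutation",
                        seed = if (is.null(seed)) sample.int(2^31 - 2, 1) else seed,
                        num.threads = 1L)
  fit$variable.importance
}

#' Gradient boosting gain importance
#'
#' Fits a squared-error boosted ensemble (learning rate `eta`) and returns
#' each marker's total gain — the summed loss reduction over every split on
#' that marker; markers never split on score 0.
#'
#' @inheritParams fit_rf_importance
#' @param cfg a [gbm_config].
#' @return Named numeric gain scores, one per marker (all non-negative).
#' @export
fit_gbm_importance <- function(x, y, cfg = gbm_config(), seed = NULL) {
  X <- as_train_matrix(x)
  if (length(unique(y)) < 2L) stop_cfg("constant phenotype")
  dtrain <- xgboost::xgb.DMatrix(X, label = as.numeric(y), nthread = 1)
  params <- list(objective = "reg:squarederror", eta = cfg$eta,
                 max_depth = cfg$max_depth, nthread = 1,
                 seed = if (is.null(seed)) 0 else as.integer(seed))
  fit <- xgboost::xgb.train(params = params, data = dtrain,
                            nrounds = cfg$n_rounds, verbose = 0)
  imp <- xgboost::xgb.importance(model = fit)
  scores <- stats::setNames(rep(0, ncol(X)), colnames(X))
  if (!is.null(imp) && nrow(imp) > 0)
    scores[imp$Feature] <- imp$Gain
  scores
}

scores_to_ranks <- function(scores) {
  rank(-scores, ties.method = "average")
}

#' Rank markers by importance averaged over model iterations
#'
#' The central fitting function.  For tree models, per-marker importance is
#' computed in `n_iter` independent iterations and converted to ranks
#' (1 = most important, ties get the average rank); the per-marker mean rank
#' over iterations is reported.  In weighted mode each iteration first draws
#' a fresh probabilistic resample of the hybrid samples using the supplied
#' `sample_weights`; in unweighted mode each iteration refits on the full
#' training set with a fresh model seed.  `model = "regression"` is the
#' deterministic single-marker OLS baseline (one iteration).
#'
#' @param x training genotypes: a [geno_matrix] or dosage matrix.
#' @param pheno a [qtl_pheno] or numeric phenotype vector.
#' @param model `"rf"`, `"gbm"` or `"regression"`.
#' @param weights optional `sample_weights` from [prioritize_samples()];
#'   when given, each iteration trains on a fresh weighted resample.
#' @param n_iter number of independent iterations (default 100).
#' @param config an [rf_config] or [gbm_config]; defaults per model.
#' @param seed master seed; per-iteration seeds are derived from it.
#' @return A `rank_table`: data frame with columns `marker_id` and
#'   `avg_rank` (plus `p_value` for regression), carrying attributes
#'   `model_label`, `n_iterations` and `weighted`.
#' @export
rank_markers <- function(x, pheno, model = c("rf", "gbm", "regression"),
                         weights = NULL, n_iter = 100, config = NULL,
                         seed = NULL) {
  model <- match.arg(model)
  y <- if (inherits(pheno, "qtl_pheno")) pheno$values else as.numeric(pheno)
  if (model == "regression")
    return(regression_ranks(x, y))
  X <- as_train_matrix(x)
  if (nrow(X) != length(y)) stop_cfg("phenotype/genotype sample count mismatch")
  if (!is_count(n_iter)) stop_cfg("'n_iter' must be a positive integer")
  config <- config %||% if (model == "rf") rf_config() else gbm_config()
  fitter <- if (model == "rf") fit_rf_importance else fit_gbm_importance
  seeds <- derive_seeds(seed, 2L * n_iter)
  m <- ncol(X)
  rank_sum <- stats::setNames(numeric(m), colnames(X))
  for (it in seq_len(n_iter)) {
    if (!is.null(weights)) {
      tr <- resample_training_set(
        if (inherits(x, "geno_matrix")) x else geno_matrix_from(X),
        if (inherits(pheno, "qtl_pheno")) pheno else
          qtl_pheno(rownames(X) %||% as.character(seq_len(nrow(X))), y),
        weights, seed = seeds[[2L * it - 1L]])
      sc <- fitter(tr$genotypes, tr$values, config, seed = seeds[[2L * it]])
    } else {
      sc <- fitter(X, y, config, seed = seeds[[2L * it]])
    }
    rank_sum <- rank_sum + scores_to_ranks(sc)
  }
  label <- paste0(model, if (!is.null(weights)) "_weighted")
  new_rank_table(colnames(X), rank_sum / n_iter, label, n_iter,
                 weighted = !is.null(weights))
}

# wrap a bare matrix for resampling
geno_matrix_from <- function(X) {
  if (is.null(rownames(X))) rownames(X) <- paste0("s", seq_len(nrow(X)))
  storage.mode(X) <- "integer"
  geno_matrix(X, population = "hybrid")
}

new_rank_table <- function(marker_ids, avg_rank, model_label, n_iterations,
                           weighted = FALSE, p_value = NULL) {
  tab <- data.frame(marker_id = marker_ids, avg_rank = as.numeric(avg_rank),
                    row.names = NULL, stringsAsFactors = FALSE)
  if (!is.null(p_value)) tab$p_value <- p_value
  structure(tab, model_label = model_label, n_iterations = n_iterations,
            weighted = weighted, class = c("rank_table", "data.frame"))
}

#' Single-marker regression baseline
#'
#' For each marker, ordinary least squares of phenotype on additive dosage;
#' markers are ranked by the ascending two-sided t-test p-value of the
#' slope (ties get the average rank).  Zero-variance markers are assigned
#' p = 1.  This reimplements the additive single-marker linear model of
#' standard GWAS tools, without covariates.
#'
#' @param x a [geno_matrix] or dosage matrix.
#' @param pheno a [qtl_pheno] or numeric phenotype vector.
#' @return A `rank_table` with columns `marker_id`, `avg_rank`, `p_value`.
#' @export
regression_ranks <- function(x, pheno) {
  X <- as_train_matrix(x)
  y <- if (inherits(pheno, "qtl_pheno")) pheno$values else as.numeric(pheno)
  n <- nrow(X)
  if (n < 3L) stop_cfg("need at least 3 samples for the regression baseline")
  if (stats::var(y) == 0) stop_cfg("constant phenotype")
  r <- suppressWarnings(as.numeric(stats::cor(X, y,
                                              use = "pairwise.complete.obs")))
  # two-sided t test on the OLS slope: t = r * sqrt((n-2) / (1-r^2))
  tt <- r * sqrt((n - 2) / pmax(1 - r^2, 0))
  p <- 2 * stats::pt(-abs(tt), df = n - 2)
  p[is.na(r)] <- 1          # zero-variance marker
  p[abs(r) >= 1] <- 0       # perfect fit
  new_rank_table(colnames(X), rank(p, ties.method = "average"),
                 "regression", 1L, p_value = p)
}

#' @export
print.rank_table <- function(x, n = 10, ...) {
  cat(sprintf("rank_table: %d markers, model %s, %d iteration(s)\n",
              nrow(x), attr(x, "model_label"), attr(x, "n_iterations")))
  ord <- order(x$avg_rank)
  print.data.frame(utils::head(x[ord, , drop = FALSE], n), row.names = FALSE)
  if (nrow(x) > n) cat("  ...", nrow(x) - n, "more markers\n")
  invisible(x)
}

#' @export
summary.rank_table <- function(object, ...) {
  cat(sprintf("Marker importance ranks (%s, %d iterations)\n",
              attr(object, "model_label"), attr(object, "n_iterations")))
  print(summary(object$avg_rank))
  invisible(object)
}

#' Plot a rank table
#'
#' Horizontal bar chart of the best (lowest) average ranks.
#'
#' @param x a `rank_table`.
#' @param n number of top markers to show.
#' @param ... passed to [graphics::barplot()].
#' @export
plot.rank_table <- function(x, n = 20, ...) {
  ord <- order(x$avg_rank)
  top <- utils::head(x[ord, ], n)
  graphics::barplot(rev(top$avg_rank), names.arg = rev(top$marker_id),
                    horiz = TRUE, las = 1,
                    xlab = "average importance rank",
                    main = attr(x, "model_label"), ...)
  invisible(x)
}

#' Extract the rank of one marker
#'
#' @param table a `rank_table`.
#' @param marker marker id.
#' @return The marker's average rank (numeric), or NA if absent.
#' @export
marker_rank <- function(table, marker) {
  i <- match(marker, table$marker_id)
  if (is.na(i)) NA_real_ else table$avg_rank[i]
}
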