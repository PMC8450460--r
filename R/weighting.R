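#' Configuration for interspecific sample weighting
#'
#' Parameters of the prioritization scheme: how many top trait-correlated
#' wild markers define the genotype distance, which phenotype quantiles
#' define trait-segregating samples in each population, and which distance
#' metric compares genotypes.
#'
#' @param top_marker_cutoff number of top wild trait-correlated markers to
#'   focus the distance on (the study sweeps 5, 10, 15, 20).
#' @param wild_seg_quantile,hybrid_seg_quantile trait-segregation quantiles
#'   in (0, 0.5) (the study sweeps 0.05, 0.10, 0.15, 0.20, 0.25).
#' @param metric `"gower"` or `"jaccard"`.
#' @param tail_mode which phenotype tail(s) count as segregating: `"both"`
#'   (default), `"upper"` or `"lower"`.
#' @param exclude_unfiltered drop hybrid samples that fail the segregation
#'   filter (probability 0) instead of retaining them at baseline
#'   probability.
#' @return A `weighting_config` list.
#' @export
weighting_config <- function(top_marker_cutoff = 10,
                             wild_seg_quantile = 0.10,
                             hybrid_seg_quantile = 0.10,
                             metric = c("gower", "jaccard"),
                             tail_mode = c("both", "upper", "lower"),
                             exclude_unfiltered = FALSE) {
  metric <- match.arg(metric)
  tail_mode <- match.arg(tail_mode)
  if (!is_count(top_marker_cutoff))
    stop_cfg("'top_marker_cutoff' must be a positive integer")
  for (q in c(wild_seg_quantile, hybrid_seg_quantile))
    if (!is.numeric(q) || q <= 0 || q >= 0.5)
      stop_cfg("segregation quantiles must be in (0, 0.5)")
  structure(list(top_marker_cutoff = as.integer(top_marker_cutoff),
                 wild_seg_quantile = wild_seg_quantile,
                 hybrid_seg_quantile = hybrid_seg_quantile,
                 metric = metric, tail_mode = tail_mode,
                 exclude_unfiltered = exclude_unfiltered),
            class = "weighting_config")
}

#' Top wild markers by trait correlation
#'
#' Ranks markers by the absolute Pearson correlation between wild phenotype
#' and allelic dosage and returns the strongest `cutoff` markers.  Ties are
#' broken by marker order in the panel.
#'
#' @param wild a wild [geno_matrix].
#' @param wild_pheno a [qtl_pheno] for the wild samples.
#' @param cutoff number of markers to keep.
#' @param restrict_to optional marker id set to rank within (e.g. the
#'   markers shared with the hybrid panel).
#' @return Character vector of `cutoff` marker ids, strongest first.
#' @export
top_wild_markers <- function(wild, wild_pheno, cutoff, restrict_to = NULL) {
  y <- wild_pheno$values
  if (stats::var(y) == 0) stop_cfg("wild phenotype has zero variance")
  ids <- marker_ids(wild)
  if (!is.null(restrict_to)) ids <- ids[ids %in% restrict_to]
  if (cutoff > length(ids))
    stop_cfg("cutoff exceeds the number of candidate markers")
  d <- wild$dosage[, ids, drop = FALSE]
  storage.mode(d) <- "double"
  r <- suppressWarnings(as.numeric(stats::cor(d, y,
                                              use = "pairwise.complete.obs")))
  r[is.na(r)] <- 0
  ids[order(-abs(r))[seq_len(cutoff)]]
}

#' Trait-segregating samples
#'
#' Samples in the phenotype tails: with `tail_mode = "both"` those at or
#' below the `q`-quantile or at or above the `(1-q)`-quantile; `"upper"` and
#' `"lower"` keep a single tail.
#'
#' @param pheno a [qtl_pheno].
#' @param q quantile in (0, 0.5).
#' @param tail_mode `"both"`, `"upper"` or `"lower"`.
#' @return Character vector of sample ids.
#' @export
segregating_samples <- function(pheno, q,
                                tail_mode = c("both", "upper", "lower")) {
  tail_mode <- match.arg(tail_mode)
  if (q <= 0 || q >= 0.5) stop_cfg("'q' must be in (0, 0.5)")
  y <- pheno$values
  if (length(y) < 2L || stats::var(y) == 0)
    stop_cfg("constant phenotype: no trait segregation")
  lo <- stats::quantile(y, q, names = FALSE)
  hi <- stats::quantile(y, 1 - q, names = FALSE)
  keep <- switch(tail_mode,
                 both  = y <= lo | y >= hi,
                 lower = y <= lo,
                 upper = y >= hi)
  pheno$sample_ids[keep]
}

#' Distance context: focus markers and their dosage ranges
#'
#' Fixes the marker subset the distances are computed over and the Gower
#' ranges `R_k`, taken over the pooled comparison set (wild reference rows
#' plus hybrid rows).
#'
#' @param pooled_dosage matrix of dosages (rows = all samples entering any
#'   comparison) restricted to the focus markers.
#' @return A `distance_context` list with `marker_ids` and `ranges`.
#' @export
distance_context <- function(pooled_dosage) {
  rng <- apply(pooled_dosage, 2, function(z)
    diff(range(z, na.rm = TRUE)))
  structure(list(marker_ids = colnames(pooled_dosage), ranges = rng),
            class = "distance_context")
}

#' Gower distance between two dosage vectors
#'
#' `S_ij = sum_k s_ijk d_ijk / sum_k d_ijk` with per-marker contribution
#' `s_ijk = |x_ik - x_jk| / R_k`; the validity weight `d_ijk` is 0 when
#' either dosage is missing or the marker's range `R_k` is 0, and 1
#' otherwise.
#'
#' @param xi,xj dosage vectors over the same markers.
#' @param ranges per-marker dosage ranges `R_k` (or a `distance_context`).
#' @return Distance in `[0, 1]`.
#' @export
gower_distance <- function(xi, xj, ranges) {
  if (inherits(ranges, "distance_context")) ranges <- ranges$ranges
  valid <- !is.na(xi) & !is.na(xj) & !is.na(ranges) & ranges > 0
  if (!any(valid)) stop_cfg("no valid markers for Gower distance")
  mean(abs(xi[valid] - xj[valid]) / ranges[valid])
}

#' Jaccard distance between two dosage vectors
#'
#' `J_ij = 1 - sum_k I_ijk / sum_k I_k`, where `I_k` is 1 when at least one
#' of the two samples has non-zero dosage at marker `k` and `I_ijk` is 1
#' when both dosages are equal; the numerator is restricted to markers with
#' `I_k = 1` so the distance stays in `[0, 1]`.
#'
#' @param xi,xj dosage vectors over the same markers.
#' @return Distance in `[0, 1]`.
#' @export
jaccard_distance <- function(xi, xj) {
  ok <- !is.na(xi) & !is.na(xj)
  active <- ok & (xi > 0 | xj > 0)
  if (!any(active)) stop_cfg("both vectors all-zero: Jaccard distance undefined")
  1 - sum(xi[active] == xj[active]) / sum(active)
}

# All pairwise distances between rows of A (hybrid) and rows of B (wild
# reference), over a fixed marker context.
distance_matrix <- function(A, B, metric, ctx) {
  out <- matrix(NA_real_, nrow(A), nrow(B),
                dimnames = list(rownames(A), rownames(B)))
  for (i in seq_len(nrow(A))) {
    xi <- A[i, ]
    for (j in seq_len(nrow(B))) {
      out[i, j] <- if (metric == "gower")
        gower_distance(xi, B[j, ], ctx) else jaccard_distance(xi, B[j, ])
    }
  }
  out
}

#' Mean distance to a reference sample set
#'
#' @param hybrid_dosage matrix of hybrid dosages over the focus markers
#'   (rows = hybrid samples).
#' @param reference_dosage matrix of wild reference dosages over the same
#'   markers.
#' @param ctx a [distance_context].
#' @param metric `"gower"` or `"jaccard"`.
#' @return Named numeric vector: per-hybrid-sample arithmetic mean distance
#'   to the reference samples.
#' @export
mean_distance <- function(hybrid_dosage, reference_dosage, ctx,
                          metric = c("gower", "jaccard")) {
  metric <- match.arg(metric)
  if (nrow(reference_dosage) == 0L) stop_cfg("empty reference set")
  rowMeans(distance_matrix(hybrid_dosage, reference_dosage, metric, ctx))
}

#' Sampling probabilities from mean distances
#'
#' Hybrid samples that passed the segregation filter receive raw weight
#' `1 - mean_distance` (closer to the wild reference = more likely to be
#' sampled); unfiltered samples receive the minimum raw weight among
#' filtered samples as a baseline (or 0 with `exclude_unfiltered`).
#' Weights are normalized to sum to 1.
#'
#' @param mean_distances per-sample mean distances in `[0, 1]` (named by
#'   sample id).
#' @param filtered_flags logical, TRUE for samples that passed the hybrid
#'   segregation filter.
#' @param exclude_unfiltered give unfiltered samples probability 0.
#' @return An object of class `sample_weights`: list with `sample_ids`,
#'   `probabilities`, `mean_distances`, `filtered_flag`.
#' @export
sampling_probabilities <- function(mean_distances, filtered_flags,
                                   exclude_unfiltered = FALSE) {
  if (length(mean_distances) != length(filtered_flags))
    stop_cfg("length mismatch")
  if (any(mean_distances < -1e-12 | mean_distances > 1 + 1e-12, na.rm = TRUE))
    stop_cfg("mean distances must lie in [0, 1]")
  if (!any(filtered_flags)) stop_cfg("no sample passed the segregation filter")
  raw <- numeric(length(mean_distances))
  raw[filtered_flags] <- 1 - mean_distances[filtered_flags]
  base <- if (exclude_unfiltered) 0 else min(raw[filtered_flags])
  raw[!filtered_flags] <- base
  if (sum(raw) <= 0) {
    warning("all raw weights zero; falling back to uniform probabilities",
            call. = FALSE)
    raw <- rep(1, length(raw))
  }
  structure(list(sample_ids = names(mean_distances) %||%
                   as.character(seq_along(mean_distances)),
                 probabilities = raw / sum(raw),
                 mean_distances = unname(mean_distances),
                 filtered_flag = filtered_flags),
            class = "sample_weights")
}

#' @export
print.sample_weights <- function(x, ...) {
  cat(sprintf("sample_weights: %d samples (%d filtered)\n",
              length(x$probabilities), sum(x$filtered_flag)))
  cat(sprintf("  probability range: %.4g - %.4g\n",
              min(x$probabilities), max(x$probabilities)))
  invisible(x)
}

#' Prioritize hybrid samples by similarity to wild material
#'
#' End-to-end weighting scheme: (1) rank shared markers by absolute
#' correlation between wild phenotype and dosage and keep the top
#' `top_marker_cutoff`; (2) keep trait-segregating wild samples (wild
#' quantile) as the reference set; (3) keep trait-segregating hybrid samples
#' (hybrid quantile); (4) compute each hybrid sample's mean Gower or Jaccard
#' distance to the reference set over the focus markers; (5) convert to
#' sampling probabilities, higher for hybrid samples genotypically closer to
#' the wild reference.
#'
#' @param hybrid,wild [geno_matrix] panels.
#' @param hybrid_pheno,wild_pheno matching [qtl_pheno] objects.
#' @param config a [weighting_config].
#' @return A `sample_weights` object over all hybrid samples.
#' @export
prioritize_samples <- function(hybrid, hybrid_pheno, wild, wild_pheno,
                               config = weighting_config()) {
  shared <- intersect_markers(wild, hybrid)
  focus <- top_wild_markers(wild, wild_pheno, config$top_marker_cutoff,
                            restrict_to = shared)
  wild_ref <- segregating_samples(wild_pheno, config$wild_seg_quantile,
                                  config$tail_mode)
  hyb_keep <- segregating_samples(hybrid_pheno, config$hybrid_seg_quantile,
                                  config$tail_mode)
  H <- hybrid$dosage[, focus, drop = FALSE]
  Wr <- wild$dosage[wild_ref, focus, drop = FALSE]
  ctx <- distance_context(rbind(Wr, H))
  d <- mean_distance(H, Wr, ctx, config$metric)
  sampling_probabilities(d, sample_ids(hybrid) %in% hyb_keep,
                         exclude_unfiltered = config$exclude_unfiltered)
}

#' Draw a probabilistically weighted training set
#'
#' Samples `n_out` hybrid individuals with replacement using the given
#' probabilities; genotype rows and phenotype entries stay paired.
#'
#' @param hybrid a [geno_matrix].
#' @param pheno the matching [qtl_pheno].
#' @param weights a `sample_weights` object (or NULL for uniform
#'   resampling).
#' @param n_out training-set size; defaults to the full hybrid panel size.
#' @param seed integer seed or NULL.
#' @return List with `genotypes` (dosage matrix, resampled rows) and
#'   `values` (numeric phenotype vector).
#' @export
resample_training_set <- function(hybrid, pheno, weights = NULL,
                                  n_out = NULL, seed = NULL) {
  n <- n_samples(hybrid)
  if (length(pheno$values) != n)
    stop_cfg("phenotype/genotype sample count mismatch")
  n_out <- n_out %||% n
  if (!is_count(n_out)) stop_cfg("'n_out' must be a positive integer")
  prob <- if (is.null(weights)) rep(1 / n, n) else weights$probabilities
  if (length(prob) != n) stop_cfg("probability/sample length mismatch")
  idx <- with_seed(seed, sample.int(n, n_out, replace = TRUE, prob = prob))
  list(genotypes = hybrid$dosage[idx, , drop = FALSE],
       values = pheno$values[idx], index = idx)
}

#' Write sample weights as TSV
#'
#' @param weights a `sample_weights` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_weights_tsv <- function(weights, path) {
  tab <- data.frame(sample_id = weights$sample_ids,
                    mean_distance = weights$mean_distances,
                    probability = weights$probabilities,
                    filtered = weights$filtered_flag)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
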