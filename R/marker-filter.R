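#' Pairwise marker correlation
#'
#' Pearson correlation between all dosage columns, using pairwise-complete
#' observations.  Zero-variance markers get correlation 0 to every other
#' marker (with a warning) so they form singleton graph components.
#'
#' @param G a [geno_matrix] with at least 2 samples.
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
pairwise_marker_correlation <- function(G) {
  if (n_samples(G) < 2L)
    stop_cfg("need at least 2 samples to compute marker correlations")
  d <- G$dosage
  storage.mode(d) <- "double"
  cc <- suppressWarnings(stats::cor(d, use = "pairwise.complete.obs"))
  if (anyNA(cc)) {
    zv <- marker_ids(G)[apply(d, 2, stats::var, na.rm = TRUE) == 0]
    if (length(zv))
      warning("zero-variance marker(s), correlations set to 0: ",
              paste(utils::head(zv, 5), collapse = ", "),
              if (length(zv) > 5) ", ...", call. = FALSE)
    cc[is.na(cc)] <- 0
  }
  diag(cc) <- 1
  cc
}

#' Connected components of the marker-correlation graph
#'
#' Markers are nodes; an edge joins two markers whose correlation exceeds
#' `threshold` (strict inequality, so a correlation equal to the threshold
#' does not connect).  By default the absolute correlation is used, since
#' anti-correlated markers are equally redundant; `signed = TRUE` uses the
#' raw coefficient.
#'
#' @param corr square symmetric correlation matrix with marker ids as
#'   dimnames.
#' @param threshold correlation cutoff (default 0.7).
#' @param signed use signed rather than absolute correlation.
#' @return A `component_partition`: list with `components` (list of marker
#'   id vectors), `threshold`, and `signed`.
#' @export
build_components <- function(corr, threshold = 0.7, signed = FALSE) {
  if (!is.matrix(corr) || nrow(corr) != ncol(corr))
    stop_cfg("'corr' must be a square matrix")
  if (is.null(colnames(corr)))
    colnames(corr) <- rownames(corr) <- paste0("m", seq_len(ncol(corr)))
  if (max(abs(corr - t(corr))) > 1e-8)
    stop_cfg("'corr' must be symmetric")
  w <- if (signed) corr else abs(corr)
  adj <- (w > threshold)
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)
  components <- split(colnames(corr), comp$membership)
  names(components) <- NULL
  structure(list(components = components, threshold = threshold,
                 signed = signed),
            class = "component_partition")
}

#' @export
print.component_partition <- function(x, ...) {
  sz <- lengths(x$components)
  cat(sprintf("component_partition: %d markers in %d components (threshold %s%.2f)\n",
              sum(sz), length(sz), if (x$signed) "r > " else "|r| > ",
              x$threshold))
  cat(sprintf("  component sizes: %s\n",
              paste(utils::head(sort(sz, decreasing = TRUE), 8), collapse = " ")))
  invisible(x)
}

#' Select one representative marker per component
#'
#' A component containing a causal marker is represented by that causal
#' marker (so rank assessment of the causal signal is not lost to a
#' correlated neighbour); other components are represented by a uniformly
#' random member.
#'
#' @param partition a `component_partition` from [build_components()].
#' @param causal_ids character vector of causal marker ids (may be empty).
#' @param seed integer seed for the random choices, or NULL.
#' @return Character vector with one marker id per component, in component
#'   order.
#' @export
select_representatives <- function(partition, causal_ids = character(0),
                                   seed = NULL) {
  if (!inherits(partition, "component_partition"))
    stop_cfg("'partition' must come from build_components()")
  with_seed(seed, {
    vapply(partition$components, function(comp) {
      hit <- intersect(causal_ids, comp)
      if (length(hit) > 1L)
        stop_cfg("component contains multiple causal markers: ",
                 paste(hit, collapse = ", "))
      if (length(hit) == 1L) return(hit)
      if (length(comp) == 1L) comp else sample(comp, 1L)
    }, character(1))
  })
}

#' Reduce a panel to approximately independent markers
#'
#' Convenience wrapper: drops zero-variance markers (with a warning),
#' builds the correlation-graph partition and keeps one representative per
#' connected component.
#'
#' @inheritParams pairwise_marker_correlation
#' @inheritParams build_components
#' @inheritParams select_representatives
#' @return List with `genotypes` (the reduced [geno_matrix]), `partition`,
#'   and `representatives`.
#' @export
filter_markers <- function(G, threshold = 0.7, causal_ids = character(0),
                           seed = NULL, signed = FALSE) {
  v <- apply(G$dosage, 2, stats::var, na.rm = TRUE)
  if (any(v == 0, na.rm = TRUE)) {
    warning(sum(v == 0, na.rm = TRUE),
            " zero-variance marker(s) dropped before graph construction",
            call. = FALSE)
    G <- G[, !is.na(v) & v > 0]
  }
  corr <- pairwise_marker_correlation(G)
  partition <- build_components(corr, threshold = threshold, signed = signed)
  reps <- select_representatives(partition, causal_ids = causal_ids,
                                 seed = seed)
  reps <- marker_ids(G)[marker_ids(G) %in% reps]   # stable marker order
  list(genotypes = G[, reps], partition = partition, representatives = reps)
}

#' Write component membership and representatives as TSV
#'
#' @param partition a `component_partition`.
#' @param representatives output of [select_representatives()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_components_tsv <- function(partition, representatives, path) {
  comp_id <- rep(seq_along(partition$components),
                 lengths(partition$components))
  marker <- unlist(partition$components)
  tab <- data.frame(component = comp_id, marker_id = marker,
                    representative = marker %in% representatives)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
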