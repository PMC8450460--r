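# Fixture builders and independent brute-force oracles used across tests.

# geno_matrix from a plain matrix, generating ids as needed
gm <- function(d, population = "hybrid") {
  d <- as.matrix(d)
  if (is.null(rownames(d))) rownames(d) <- sprintf("s%03d", seq_len(nrow(d)))
  if (is.null(colnames(d))) colnames(d) <- sprintf("m%03d", seq_len(ncol(d)))
  geno_matrix(d, population = population)
}

# random dosage panel with independent markers
random_panel <- function(n, m, population = "hybrid", maf = 0.3) {
  d <- matrix(rbinom(n * m, 2L, maf), n, m)
  gm(d, population)
}

# F2-style dosage vector: frequencies 1:2:1
f2_dosage <- function(n) rbinom(n, 1L, 0.5) + rbinom(n, 1L, 0.5)

# Brute-force Gower distance: explicit per-marker loop over the printed
# formula, independent of the vectorised implementation.
gower_loop <- function(xi, xj, ranges) {
  num <- 0; den <- 0
  for (k in seq_along(xi)) {
    valid <- !is.na(xi[k]) && !is.na(xj[k]) && !is.na(ranges[k]) &&
      ranges[k] > 0
    if (valid) {
      num <- num + abs(xi[k] - xj[k]) / ranges[k]
      den <- den + 1
    }
  }
  num / den
}

# Brute-force Jaccard distance per the printed formula.
jaccard_loop <- function(xi, xj) {
  num <- 0; den <- 0
  for (k in seq_along(xi)) {
    if (is.na(xi[k]) || is.na(xj[k])) next
    if (xi[k] > 0 || xj[k] > 0) {
      den <- den + 1
      if (xi[k] == xj[k]) num <- num + 1
    }
  }
  1 - num / den
}

# Brute-force connected components by transitive closure of the adjacency
# relation (|r| > threshold), for matrices small enough to iterate.
components_closure <- function(corr, threshold = 0.7) {
  m <- ncol(corr)
  adj <- abs(corr) > threshold
  diag(adj) <- TRUE
  reach <- adj
  for (it in seq_len(m)) {
    new <- (reach %*% reach) > 0
    if (all(new == reach)) break
    reach <- new
  }
  membership <- integer(m)
  comp <- 0L
  for (i in seq_len(m)) {
    if (membership[i] == 0L) {
      comp <- comp + 1L
      membership[reach[i, ]] <- comp
    }
  }
  split(colnames(corr) %||% as.character(seq_len(m)), membership)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# canonical form of a partition for set comparison
canon_partition <- function(components) {
  comps <- unname(lapply(components, function(x) sort(as.character(x))))
  comps[order(vapply(comps, `[`, character(1), 1))]
}

# Manual out-of-bag permutation importance for a ranger forest fitted with
# keep.inbag = TRUE: permute one marker, re-predict per tree, average the
# increase in OOB squared error.  Independent of ranger's internal
# importance computation (its permutation draws differ).
manual_perm_importance <- function(fit, X, y, n_perm = 5) {
  preds <- predict(fit, data = X, predict.all = TRUE)$predictions
  inbag <- simplify2array(fit$inbag.counts)
  oob <- inbag == 0
  ntree <- ncol(preds)
  tree_err <- function(p) {
    vapply(seq_len(ntree),
           function(t) mean((p[oob[, t], t] - y[oob[, t]])^2), numeric(1))
  }
  base <- tree_err(preds)
  vapply(colnames(X), function(v) {
    mean(replicate(n_perm, {
      Xp <- X
      Xp[, v] <- sample(Xp[, v])
      mean(tree_err(predict(fit, data = Xp,
                            predict.all = TRUE)$predictions) - base)
    }))
  }, numeric(1))
}

# small wild/hybrid pair with a guaranteed strong causal marker
toy_cross <- function(seed = 1, n_wild = 80, n_hybrid = 60, n_markers = 60,
                      block = 3) {
  cfg <- sim_pop_config(n_wild = n_wild, n_hybrid = n_hybrid,
                        n_markers = n_markers, ld_block_size = block,
                        seed = seed)
  wild <- simulate_wild_population(cfg)
  hybrid <- simulate_f2_population(wild, cfg)
  list(wild = wild, hybrid = hybrid, cfg = cfg)
}
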