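#' Simulation configuration for synthetic chickpea-like panels
#'
#' Parameters controlling the synthetic wild panel and the F2 hybrid panel
#' derived from it.  Defaults emulate the Bari-style material: a wild panel
#' of 143 samples, an F2 panel of 140 samples descended from 20 wild parent
#' lines crossed to a fixed homozygous cultivar, markers organised in
#' linkage-disequilibrium blocks.
#'
#' @param n_wild number of wild samples.
#' @param n_hybrid number of F2 hybrid samples.
#' @param n_markers number of markers in the wild panel.
#' @param ld_block_size markers per linkage block; 1 gives independent
#'   markers.
#' @param wild_maf_range interval in (0, 0.5] from which per-marker wild
#'   minor-allele frequencies are drawn uniformly.
#' @param shared_marker_fraction fraction in (0, 1] of hybrid markers whose
#'   ids overlap the wild panel; the rest are relabelled as hybrid-private.
#' @param n_parents number of wild lines used as F2 parents.
#' @param recomb_rate per-adjacent-marker recombination probability within a
#'   block (between blocks recombination is free, 0.5).
#' @param ld_rho Gaussian-copula correlation tying haplotype alleles within
#'   a block; controls within-block dosage correlation.
#' @param seed integer seed, or NULL to use the ambient RNG stream.
#' @return A `sim_pop_config` list.
#' @export
sim_pop_config <- function(n_wild = 143, n_hybrid = 140, n_markers = 1946,
                           ld_block_size = 4,
                           wild_maf_range = c(0.1, 0.5),
                           shared_marker_fraction = 0.8,
                           n_parents = 20, recomb_rate = 0.02,
                           ld_rho = 0.98, seed = NULL) {
  for (nm in c("n_wild", "n_hybrid", "n_markers", "ld_block_size",
               "n_parents")) {
    if (!is_count(get(nm))) stop_cfg("'", nm, "' must be a positive integer")
  }
  if (length(wild_maf_range) != 2L || any(is.na(wild_maf_range)) ||
      wild_maf_range[1] > wild_maf_range[2] ||
      wild_maf_range[1] <= 0 || wild_maf_range[2] > 0.5)
    stop_cfg("'wild_maf_range' must be an interval within (0, 0.5]")
  if (shared_marker_fraction <= 0 || shared_marker_fraction > 1)
    stop_cfg("'shared_marker_fraction' must be in (0, 1]")
  if (recomb_rate < 0 || recomb_rate > 0.5)
    stop_cfg("'recomb_rate' must be in [0, 0.5]")
  if (ld_rho < 0 || ld_rho >= 1)
    stop_cfg("'ld_rho' must be in [0, 1)")
  structure(list(n_wild = as.integer(n_wild),
                 n_hybrid = as.integer(n_hybrid),
                 n_markers = as.integer(n_markers),
                 ld_block_size = as.integer(ld_block_size),
                 wild_maf_range = as.numeric(wild_maf_range),
                 shared_marker_fraction = shared_marker_fraction,
                 n_parents = as.integer(n_parents),
                 recomb_rate = recomb_rate, ld_rho = ld_rho,
                 seed = if (is.null(seed)) NULL else as.integer(seed)),
            class = "sim_pop_config")
}

# Block index per marker.
marker_blocks <- function(n_markers, block_size) {
  rep(seq_len(ceiling(n_markers / block_size)),
      each = block_size)[seq_len(n_markers)]
}

#' Simulate a wild genotype panel with blockwise LD
#'
#' Each sample carries two haplotypes.  Alleles are generated through a
#' Gaussian copula: haplotype alleles at markers within the same linkage
#' block share a latent block factor (`ld_rho`), so within-block dosage
#' correlation exceeds between-block correlation; per-marker minor-allele
#' frequencies are drawn uniformly from `wild_maf_range`.
#'
#' @param cfg a [sim_pop_config].
#' @return A wild-labelled [geno_matrix] (`n_wild` x `n_markers`).
#' @export
simulate_wild_population <- function(cfg) {
  if (!inherits(cfg, "sim_pop_config")) stop_cfg("'cfg' must be a sim_pop_config")
  with_seed(cfg$seed, {
    m <- cfg$n_markers
    nh <- 2L * cfg$n_wild                      # haplotypes
    blocks <- marker_blocks(m, cfg$ld_block_size)
    nb <- max(blocks)
    # markers on the same haplotype block share their allele frequency:
    # strong within-block dosage correlation is impossible otherwise
    p <- stats::runif(nb, cfg$wild_maf_range[1],
                      cfg$wild_maf_range[2])[blocks]
    g <- matrix(stats::rnorm(nh * nb), nh, nb)       # latent block factors
    e <- matrix(stats::rnorm(nh * m), nh, m)         # marker-specific noise
    z <- sqrt(cfg$ld_rho) * g[, blocks, drop = FALSE] +
      sqrt(1 - cfg$ld_rho) * e
    hap <- sweep(z, 2, stats::qnorm(p), "<") + 0L    # allele 1 w.p. p
    dos <- hap[seq_len(cfg$n_wild), , drop = FALSE] +
      hap[cfg$n_wild + seq_len(cfg$n_wild), , drop = FALSE]
    dimnames(dos) <- list(sprintf("W%03d", seq_len(cfg$n_wild)),
                          sprintf("mk%05d", seq_len(m)))
    out <- geno_matrix(dos, population = "wild")
    # keep the phased haplotypes so a cross can transmit real haplotypes
    attr(out, "haplotypes") <- hap
    out
  })
}

# Recombination probability between adjacent markers: recomb_rate within a
# block, free recombination (0.5) across block boundaries.
recomb_vector <- function(blocks, recomb_rate) {
  m <- length(blocks)
  if (m == 1L) return(numeric(0))
  r <- rep(recomb_rate, m - 1L)
  r[blocks[-m] != blocks[-1L]] <- 0.5
  r
}

# One gamete from a pair of phased haplotypes: Markov chain over markers,
# switching haplotype with probability r between adjacent markers.
make_gamete <- function(h1, h2, r) {
  m <- length(h1)
  start <- stats::rbinom(1L, 1L, 0.5)
  switches <- if (m > 1L) stats::rbinom(m - 1L, 1L, r) else integer(0)
  state <- (start + c(0L, cumsum(switches))) %% 2L   # 0 -> h1, 1 -> h2
  ifelse(state == 0L, h1, h2)
}

# Random phase for a dosage vector when true haplotypes are unknown:
# heterozygous sites within one LD block are phased coherently (their
# alternate alleles go to the same haplotype), consistent with the strong
# within-block LD the panels carry.
phase_dosage <- function(dos, blocks) {
  h1 <- as.integer(dos == 2L)
  h2 <- h1
  het <- dos == 1L
  if (any(het)) {
    to1 <- (stats::rbinom(max(blocks), 1L, 0.5) == 1L)[blocks]
    h1[het & to1] <- 1L
    h2[het & !to1] <- 1L
  }
  list(h1, h2)
}

#' Simulate an F2 hybrid panel from a wild panel
#'
#' Each F2 individual descends from one wild parent (drawn from
#' `cfg$n_parents` wild lines) crossed to a fixed homozygous cultivar parent
#' carrying dosage 0 everywhere, with the F1 selfed.  Gametes recombine
#' between adjacent markers at `cfg$recomb_rate` within blocks and freely
#' across blocks.  Markers where the wild parent carries the non-cultivar
#' allele segregate in the F2; a fraction `1 - shared_marker_fraction` of
#' markers is relabelled with hybrid-private ids.
#'
#' @param wild a wild [geno_matrix].
#' @param cfg a [sim_pop_config]; `cfg$seed` (when set) controls parent
#'   choice, recombination and marker relabelling.
#' @return A hybrid-labelled [geno_matrix] (`n_hybrid` x `n_markers(wild)`).
#' @export
simulate_f2_population <- function(wild, cfg) {
  if (!inherits(wild, "geno_matrix") || n_samples(wild) == 0L)
    stop_cfg("'wild' must be a non-empty geno_matrix")
  if (!inherits(cfg, "sim_pop_config")) stop_cfg("'cfg' must be a sim_pop_config")
  with_seed(cfg$seed, {
    m <- n_markers(wild)
    blocks <- marker_blocks(m, cfg$ld_block_size)
    r <- recomb_vector(blocks, cfg$recomb_rate)
    np <- min(cfg$n_parents, n_samples(wild))
    parents <- sample(n_samples(wild), np)
    hap <- attr(wild, "haplotypes")
    phased <- if (!is.null(hap)) {
      nw <- n_samples(wild)
      lapply(parents, function(i) list(hap[i, ], hap[nw + i, ]))
    } else {
      lapply(parents, function(i) phase_dosage(wild$dosage[i, ], blocks))
    }
    zero <- integer(m)
    dos <- matrix(0L, cfg$n_hybrid, m)
    for (i in seq_len(cfg$n_hybrid)) {
      ph <- phased[[sample.int(np, 1L)]]
      wild_gamete <- make_gamete(ph[[1]], ph[[2]], r)   # wild -> F1
      # F1 haplotypes: wild-derived gamete and the cultivar's all-zero one;
      # selfing draws two independent recombinant F1 gametes.
      g1 <- make_gamete(wild_gamete, zero, r)
      g2 <- make_gamete(wild_gamete, zero, r)
      dos[i, ] <- g1 + g2
    }
    ids <- marker_ids(wild)
    n_private <- round((1 - cfg$shared_marker_fraction) * m)
    if (n_private > 0) {
      priv <- sample(m, n_private)
      ids[priv] <- sprintf("hyb%05d", seq_len(n_private))
    }
    dimnames(dos) <- list(sprintf("H%03d", seq_len(cfg$n_hybrid)), ids)
    geno_matrix(dos, population = "hybrid")
  })
}

#' Markers shared between two panels
#'
#' @param wild,hybrid non-empty [geno_matrix] objects.
#' @return Character vector of marker ids present in both panels, in hybrid
#'   marker order.
#' @export
intersect_markers <- function(wild, hybrid) {
  if (n_markers(wild) == 0L || n_markers(hybrid) == 0L)
    stop_cfg("both panels must contain markers")
  shared <- marker_ids(hybrid)[marker_ids(hybrid) %in% marker_ids(wild)]
  if (length(shared) == 0L)
    stop_cfg("no markers shared between the panels: no candidate causal markers")
  shared
}
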