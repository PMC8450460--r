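#' Phenotype vector with simulation provenance
#'
#' @param sample_ids character vector of sample ids.
#' @param values numeric trait values, one per sample.
#' @param causal_marker id of the causal marker (or NULL for real traits).
#' @param suppressor_marker id of the trans-acting suppressor marker, or
#'   NULL when no suppression was applied.
#' @param target_ve target fraction of variance explained, in (0, 1].
#' @param effect additive effect per dosage unit.
#' @param suppressed_mask logical per-sample flag, TRUE where the genetic
#'   contribution was suppressed.
#' @return An object of class `qtl_pheno`.
#' @export
qtl_pheno <- function(sample_ids, values, causal_marker = NULL,
                      suppressor_marker = NULL, target_ve = NA_real_,
                      effect = NA_real_, suppressed_mask = NULL) {
  if (length(sample_ids) != length(values))
    stop_cfg("'sample_ids' and 'values' lengths differ")
  if (is.null(suppressed_mask))
    suppressed_mask <- rep(FALSE, length(values))
  if (length(suppressed_mask) != length(values))
    stop_cfg("'suppressed_mask' length mismatch")
  if (is.null(suppressor_marker) && any(suppressed_mask))
    stop_cfg("suppressed_mask must be all-FALSE without a suppressor marker")
  if (!is.na(target_ve) && (target_ve <= 0 || target_ve > 1))
    stop_cfg("'target_ve' must be in (0, 1]")
  structure(list(sample_ids = as.character(sample_ids),
                 values = as.numeric(values),
                 causal_marker = causal_marker,
                 suppressor_marker = suppressor_marker,
                 target_ve = target_ve, effect = effect,
                 suppressed_mask = suppressed_mask),
            class = "qtl_pheno")
}

#' @export
print.qtl_pheno <- function(x, ...) {
  cat(sprintf("qtl_pheno: %d samples", length(x$values)))
  if (!is.null(x$causal_marker))
    cat(sprintf(", causal %s (target VE %.2f)", x$causal_marker, x$target_ve))
  if (!is.null(x$suppressor_marker))
    cat(sprintf(", suppressed by %s in %d samples",
                x$suppressor_marker, sum(x$suppressed_mask)))
  cat("\n")
  invisible(x)
}

#' Select a causal marker with higher wild than hybrid MAF
#'
#' Samples uniformly among shared markers whose wild minor-allele frequency
#' is at least `maf_ratio_threshold` times the hybrid minor-allele
#' frequency.  Markers monomorphic in the hybrid panel are excluded (a
#' causal marker must segregate to be mappable).
#'
#' @param wild,hybrid [geno_matrix] panels with overlapping markers.
#' @param maf_ratio_threshold minimum wild/hybrid MAF ratio (default 1.5).
#' @param seed integer seed or NULL.
#' @return A single marker id.
#' @export
select_causal_marker <- function(wild, hybrid, maf_ratio_threshold = 1.5,
                                 seed = NULL) {
  shared <- intersect_markers(wild, hybrid)
  mw <- minor_allele_freq(wild[, shared])
  mh <- minor_allele_freq(hybrid[, shared])
  ratio <- ifelse(mh > 0, mw / mh, NA_real_)
  eligible <- shared[!is.na(ratio) & ratio >= maf_ratio_threshold]
  if (length(eligible) == 0L)
    stop_cfg("no shared marker passes the MAF-ratio threshold ",
             maf_ratio_threshold, "; best observed ratio: ",
             signif(max(ratio, na.rm = TRUE), 3))
  if (length(eligible) == 1L) return(eligible)
  with_seed(seed, sample(eligible, 1L))
}

#' Select a trans-acting suppressor marker
#'
#' Uniform draw from hybrid markers, excluding the causal marker and (when a
#' partition is supplied) every marker in the causal marker's correlation
#' component, so the suppressor is genetically unlinked to the signal it
#' masks.
#'
#' @param hybrid a [geno_matrix].
#' @param causal causal marker id.
#' @param partition optional `component_partition` of the hybrid markers.
#' @param seed integer seed or NULL.
#' @return A single marker id.
#' @export
select_suppressor <- function(hybrid, causal, partition = NULL, seed = NULL) {
  excl <- causal
  if (!is.null(partition)) {
    in_comp <- vapply(partition$components, function(cmp) causal %in% cmp,
                      logical(1))
    if (any(in_comp)) excl <- partition$components[[which(in_comp)[1]]]
  }
  pool <- setdiff(marker_ids(hybrid), excl)
  pool <- pool[apply(hybrid$dosage[, pool, drop = FALSE], 2,
                     function(z) stats::var(z, na.rm = TRUE) > 0)]
  if (length(pool) == 0L) stop_cfg("no eligible suppressor marker")
  if (length(pool) == 1L) return(pool)
  with_seed(seed, sample(pool, 1L))
}

#' Simulate an additive phenotype at a target variance explained
#'
#' The trait is `effect * dosage + noise` with i.i.d. Gaussian noise whose
#' variance is set by the closed form
#' `sigma^2 = Var(effect * dosage) * (1 - VE) / VE`, so the expected
#' fraction of phenotypic variance explained by the causal marker equals
#' `target_ve`.  `target_ve = 1` gives a noiseless trait.
#'
#' @param G a [geno_matrix].
#' @param causal id of the causal marker; its dosage must vary.
#' @param target_ve target variance explained, in (0, 1].
#' @param effect additive effect per dosage unit (default 1).
#' @param seed integer seed or NULL.
#' @return A [qtl_pheno].
#' @export
simulate_phenotype <- function(G, causal, target_ve, effect = 1, seed = NULL) {
  if (!causal %in% marker_ids(G))
    stop_cfg("causal marker '", causal, "' not in the panel")
  if (target_ve <= 0 || target_ve > 1)
    stop_cfg("'target_ve' must be in (0, 1]")
  g <- G$dosage[, causal]
  if (anyNA(g)) stop_cfg("causal marker has missing dosages")
  vg <- stats::var(effect * g)
  if (vg == 0) stop_cfg("causal marker '", causal, "' has zero dosage variance")
  sigma2 <- vg * (1 - target_ve) / target_ve
  values <- with_seed(seed,
                      effect * g + stats::rnorm(length(g), 0, sqrt(sigma2)))
  qtl_pheno(sample_ids = sample_ids(G), values = values,
            causal_marker = causal, target_ve = target_ve, effect = effect)
}

#' Apply trans-regulatory suppression to a simulated phenotype
#'
#' In samples where the suppressor marker carries at least one non-cultivar
#' allele (dosage > 0), the genetic contribution of the causal marker is
#' attenuated by `factor` (default 1: complete removal, leaving only the
#' noise term).  Other samples are untouched.
#'
#' @param pheno a [qtl_pheno] produced by [simulate_phenotype()].
#' @param G the [geno_matrix] the phenotype was simulated from.
#' @param suppressor id of the suppressor marker; must differ from the
#'   causal marker.
#' @param factor suppression factor in `[0, 1]`; 1 removes the genetic term
#'   entirely.
#' @return The modified [qtl_pheno] with `suppressed_mask` set.
#' @export
apply_trans_suppression <- function(pheno, G, suppressor, factor = 1) {
  if (is.null(pheno$causal_marker))
    stop_cfg("'pheno' must carry a causal marker")
  if (identical(suppressor, pheno$causal_marker))
    stop_cfg("suppressor must differ from the causal marker")
  if (!suppressor %in% marker_ids(G))
    stop_cfg("suppressor marker '", suppressor, "' not in the panel")
  if (factor < 0 || factor > 1) stop_cfg("'factor' must be in [0, 1]")
  mask <- G$dosage[, suppressor] > 0
  mask[is.na(mask)] <- FALSE
  g <- G$dosage[, pheno$causal_marker]
  values <- pheno$values
  values[mask] <- values[mask] - factor * pheno$effect * g[mask]
  qtl_pheno(sample_ids = pheno$sample_ids, values = values,
            causal_marker = pheno$causal_marker,
            suppressor_marker = suppressor,
            target_ve = pheno$target_ve, effect = pheno$effect,
            suppressed_mask = mask)
}

#' Realized variance explained
#'
#' Coefficient of determination from the least-squares regression of trait
#' values on causal-marker dosage.
#'
#' @param pheno a [qtl_pheno] (or numeric trait vector).
#' @param dosage per-sample dosages of the marker of interest.
#' @return R-squared, a fraction in `[0, 1]`.
#' @export
realized_variance_explained <- function(pheno, dosage) {
  y <- if (inherits(pheno, "qtl_pheno")) pheno$values else as.numeric(pheno)
  if (length(y) != length(dosage)) stop_cfg("length mismatch")
  if (stats::var(y) == 0 || stats::var(dosage) == 0)
    stop_cfg("degenerate variance in phenotype or dosage")
  as.numeric(stats::cor(y, dosage)^2)
}
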