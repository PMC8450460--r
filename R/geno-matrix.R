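#' Genotype matrix container
#'
#' A `geno_matrix` holds an additive-dosage genotype table for one
#' population: samples in rows, markers in columns, entries counting copies
#' of the non-cultivar (alternate/wild) allele, so each non-missing entry is
#' 0, 1 or 2.  Missing genotypes are stored as `NA`.  The population label
#' distinguishes the wild panel from an F2 hybrid panel.
#'
#' @param dosage numeric or integer matrix with unique row names (sample
#'   ids) and unique column names (marker ids); entries in `{0, 1, 2}` or
#'   `NA`.
#' @param population `"wild"` or `"hybrid"`.
#' @return An object of class `geno_matrix`: a list with elements `dosage`
#'   (integer matrix) and `population`.
#' @examples
#' g <- geno_matrix(matrix(c(0L, 1L, 2L, 1L), 2, 2,
#'                         dimnames = list(c("s1", "s2"), c("m1", "m2"))),
#'                  population = "wild")
#' marker_ids(g)
#' @export
geno_matrix <- function(dosage, population = c("wild", "hybrid")) {
  population <- match.arg(population)
  if (!is.matrix(dosage))
    stop_cfg("'dosage' must be a matrix")
  if ((is.null(rownames(dosage)) && nrow(dosage) > 0) ||
      (is.null(colnames(dosage)) && ncol(dosage) > 0))
    stop_cfg("'dosage' must have sample ids as row names and marker ids as column names")
  if (anyDuplicated(rownames(dosage)))
    stop_cfg("sample ids must be unique")
  if (anyDuplicated(colnames(dosage)))
    stop_cfg("marker ids must be unique")
  storage.mode(dosage) <- "integer"
  ok <- is.na(dosage) | dosage == 0L | dosage == 1L | dosage == 2L
  if (!all(ok))
    stop_cfg("dosage entries must be 0, 1, 2 or NA; offending value(s): ",
             paste(utils::head(unique(dosage[!ok]), 5), collapse = ", "))
  structure(list(dosage = dosage, population = population),
            class = "geno_matrix")
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat(sprintf("geno_matrix: %d %s samples x %d markers\n",
              n_samples(x), x$population, n_markers(x)))
  nm <- sum(is.na(x$dosage))
  if (nm > 0) cat(sprintf("  missing entries: %d\n", nm))
  invisible(x)
}

#' @rdname geno_matrix
#' @param x a `geno_matrix`.
#' @param ... ignored.
#' @export
as.matrix.geno_matrix <- function(x, ...) x$dosage

#' @rdname geno_matrix
#' @export
sample_ids <- function(x) rownames(x$dosage)

#' @rdname geno_matrix
#' @export
marker_ids <- function(x) colnames(x$dosage)

#' @rdname geno_matrix
#' @export
n_samples <- function(x) nrow(x$dosage)

#' @rdname geno_matrix
#' @export
n_markers <- function(x) ncol(x$dosage)

#' @param i,j sample and marker indices (numeric, logical or character), as
#'   for matrix subsetting; either may be missing.
#' @rdname geno_matrix
#' @export
`[.geno_matrix` <- function(x, i, j, ...) {
  d <- x$dosage[i, j, drop = FALSE]
  geno_matrix(d, population = x$population)
}

#' Per-marker allele and minor-allele frequencies
#'
#' Frequencies of the counted (non-cultivar) allele and the minor allele,
#' computed from non-missing dosages.
#'
#' @param G a [geno_matrix].
#' @return Named numeric vector, one entry per marker.
#' @export
allele_freq <- function(G) {
  colMeans(G$dosage, na.rm = TRUE) / 2
}

#' @rdname allele_freq
#' @export
minor_allele_freq <- function(G) {
  p <- allele_freq(G)
  pmin(p, 1 - p)
}
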