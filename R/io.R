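#' Read genotypes from a VCF file
#'
#' Converts diploid GT fields to alternate-allele dosage (0/1/2).  Only
#' biallelic sites are supported; missing genotypes (`./.` or `.|.`) become
#' `NA`.
#'
#' @param path path to a VCF (v4.x) file.
#' @param population population label for the resulting matrix.
#' @return A [geno_matrix] (samples x variants).
#' @export
read_vcf <- function(path, population = c("hybrid", "wild")) {
  population <- match.arg(population)
  if (!file.exists(path)) stop_cfg("VCF file not found: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix)))                       # single-variant files
    fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  alt <- fix[, "ALT"]
  if (any(grepl(",", alt, fixed = TRUE))) {
    bad <- which(grepl(",", alt, fixed = TRUE))[1]
    stop_cfg("multi-allelic site not supported: ",
             fix[bad, "CHROM"], ":", fix[bad, "POS"])
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  ids <- fix[, "ID"]
  noid <- is.na(ids) | ids == "."
  ids[noid] <- paste0(fix[noid, "CHROM"], "_", fix[noid, "POS"])
  rownames(gt) <- ids
  dos <- apply(gt, c(1, 2), gt_to_dosage)
  dimnames(dos) <- dimnames(gt)
  geno_matrix(t(dos), population = population)
}

gt_to_dosage <- function(g) {
  if (is.na(g)) return(NA_integer_)
  alleles <- strsplit(g, "[/|]")[[1]]
  if (any(alleles == ".")) return(NA_integer_)
  a <- suppressWarnings(as.integer(alleles))
  if (length(a) != 2L || anyNA(a))
    stop_cfg("malformed GT field: '", g, "'")
  if (any(a > 1L))
    stop_cfg("multi-allelic GT not supported: '", g, "'")
  sum(a)
}

#' Read genotypes from PLINK additive-dosage text
#'
#' Reads the whitespace-delimited `.raw`-style dialect: a header line, the
#' identifier columns `FID IID` (optionally followed by the standard
#' `PAT MAT SEX PHENOTYPE`), then one additive-dosage column per marker.
#' `NA` entries become missing.
#'
#' @param path path to the text file.
#' @param population population label.
#' @return A [geno_matrix].
#' @export
read_plink_raw <- function(path, population = c("hybrid", "wild")) {
  population <- match.arg(population)
  if (!file.exists(path)) stop_cfg("file not found: ", path)
  lines <- readLines(path, n = 2L)
  if (length(lines) == 0L) stop_cfg("empty file: ", path)
  if (length(lines) == 1L) {             # header only: no samples
    hdr <- strsplit(trimws(lines), "[ \t]+")[[1]]
    if (!identical(hdr[1:2], c("FID", "IID")))
      stop_cfg("expected header starting with FID IID in '", path, "'")
    markers <- setdiff(hdr, c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE"))
    dos <- matrix(integer(0), 0, length(markers),
                  dimnames = list(character(0), markers))
    return(geno_matrix(dos, population = population))
  }
  tab <- tryCatch(
    utils::read.table(path, header = TRUE, stringsAsFactors = FALSE,
                      check.names = FALSE),
    error = function(e) stop_cfg("parse error in '", path, "': ",
                                 conditionMessage(e)))
  if (!all(c("FID", "IID") %in% names(tab)[1:2]))
    stop_cfg("expected header starting with FID IID in '", path, "'")
  meta <- intersect(c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE"),
                    names(tab))
  markers <- setdiff(names(tab), meta)
  dos <- as.matrix(tab[, markers, drop = FALSE])
  if (nrow(dos) == 0L) {
    dos <- matrix(integer(0), 0, length(markers),
                  dimnames = list(character(0), markers))
    return(geno_matrix(dos, population = population))
  }
  bad <- !is.na(dos) & !(dos %in% c(0, 1, 2))
  if (any(bad))
    stop_cfg("dosage outside {0,1,2} in '", path, "': value ",
             dos[which(bad)[1]])
  rownames(dos) <- as.character(tab$IID)
  geno_matrix(dos, population = population)
}

#' Write genotypes as PLINK additive-dosage text
#'
#' Inverse of [read_plink_raw()]: header `FID IID <marker ids>`, one row per
#' sample, dosage counting the non-cultivar allele, missing as `NA`.
#'
#' @param G a [geno_matrix].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_plink_raw <- function(G, path) {
  tab <- data.frame(FID = sample_ids(G), IID = sample_ids(G),
                    G$dosage, check.names = FALSE)
  utils::write.table(tab, path, sep = " ", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read/write genotype TSV (samples x markers)
#'
#' Plain TSV with a `sample_id` column followed by one column per marker.
#'
#' @param G a [geno_matrix].
#' @param path file path.
#' @param population population label (reader only).
#' @return The reader returns a [geno_matrix]; the writer returns `path`
#'   invisibly.
#' @export
write_geno_tsv <- function(G, path) {
  tab <- data.frame(sample_id = sample_ids(G), G$dosage, check.names = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_geno_tsv
#' @export
read_geno_tsv <- function(path, population = c("hybrid", "wild")) {
  population <- match.arg(population)
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE)
  if (names(tab)[1] != "sample_id")
    stop_cfg("expected first column 'sample_id' in '", path, "'")
  dos <- as.matrix(tab[, -1, drop = FALSE])
  rownames(dos) <- as.character(tab$sample_id)
  geno_matrix(dos, population = population)
}

#' Read/write phenotype TSV
#'
#' Two tab-separated columns, `sample_id` and `value`.  The writer also
#' emits a JSON sidecar (`<path>.json`) recording the simulation provenance
#' (causal marker, suppressor, target variance explained) when present.
#'
#' @param pheno a [qtl_pheno].
#' @param path file path.
#' @return The reader returns a [qtl_pheno]; the writer returns `path`
#'   invisibly.
#' @export
write_pheno_tsv <- function(pheno, path) {
  tab <- data.frame(sample_id = pheno$sample_ids, value = pheno$values)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  side <- list(causal_marker = pheno$causal_marker,
               suppressor_marker = pheno$suppressor_marker,
               target_ve = pheno$target_ve, effect = pheno$effect)
  jsonlite::write_json(side[!vapply(side, is.null, logical(1))],
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_pheno_tsv
#' @export
read_pheno_tsv <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  if (!all(c("sample_id", "value") %in% names(tab)))
    stop_cfg("expected columns 'sample_id' and 'value' in '", path, "'")
  side <- if (file.exists(paste0(path, ".json")))
    jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  else list()
  qtl_pheno(sample_ids = as.character(tab$sample_id),
            values = as.numeric(tab$value),
            causal_marker = side$causal_marker,
            suppressor_marker = side$suppressor_marker,
            target_ve = side$target_ve %||% NA_real_,
            effect = side$effect %||% NA_real_)
}
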