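# PheWAS-style pleiotropy: associations per SNP across a phenotype panel.

#' Construct a p-value matrix container
#'
#' @param p Numeric SNP x phenotype matrix of p-values, entries in (0, 1]
#'   or `NA` for untested pairs.
#' @param snp_ids Character vector of SNP ids (rows).
#' @param maf Per-SNP minor-allele frequency, in (0, 0.5].
#' @param phen_ids Character vector of phenotype ids (columns).
#' @return A `pvalue_matrix` object.
#' @export
pvalue_matrix <- function(p, snp_ids, maf, phen_ids) {
  p <- as.matrix(p)
  stopifnot(nrow(p) == length(snp_ids), nrow(p) == length(maf),
            ncol(p) == length(phen_ids),
            all(maf > 0 & maf <= 0.5),
            all(is.na(p) | (p > 0 & p <= 1)))
  dimnames(p) <- list(snp_ids, phen_ids)
  structure(list(p = p, snp_ids = snp_ids, maf = maf, phen_ids = phen_ids),
            class = "pvalue_matrix")
}

#' Count associations per SNP
#'
#' For each SNP, the number of phenotypes with p strictly below the
#' threshold. Missing entries never count.
#'
#' @param m A [pvalue_matrix()].
#' @param threshold P-value cutoff (default 5e-4, strict inequality).
#' @return Named integer vector of per-SNP counts.
#' @export
count_associations <- function(m, threshold = 5e-4) {
  stopifnot(inherits(m, "pvalue_matrix"), threshold > 0)
  counts <- rowSums(m$p < threshold, na.rm = TRUE)
  storage.mode(counts) <- "integer"
  counts
}

#' Genome-background association-count summary
#'
#' Mean and median association count over all SNPs and, optionally, over
#' the stratum with minor-allele frequency strictly above `maf_min`.
#'
#' @param counts Named per-SNP counts from [count_associations()].
#' @param maf Per-SNP minor-allele frequencies, aligned with `counts`.
#' @param maf_min Optional MAF lower bound for the stratum (strict).
#' @return List with `mean`, `median`, and when `maf_min` is given
#'   `stratum_mean`, `stratum_median`, `stratum_n`.
#' @export
background_summary <- function(counts, maf, maf_min = NULL) {
  stopifnot(length(counts) == length(maf))
  out <- list(mean = mean(counts), median = stats::median(counts))
  if (!is.null(maf_min)) {
    keep <- maf > maf_min
    if (!any(keep)) stop("empty MAF stratum: no SNP with maf > ", maf_min)
    out$stratum_mean <- mean(counts[keep])
    out$stratum_median <- stats::median(counts[keep])
    out$stratum_n <- sum(keep)
  }
  out
}

#' Summarise association counts over disease locus sets
#'
#' For each disease, the mean association count over its established
#' susceptibility SNPs and the standard error (sample SD / sqrt(set
#' size)). SNPs missing from the count vector are reported and skipped;
#' sets resolving to fewer than two SNPs get `NA` SE with a warning.
#'
#' @param counts Named per-SNP counts from [count_associations()].
#' @param sets Named list: disease name -> character vector of SNP ids.
#' @return data.frame with columns `disease`, `n_loci`, `mean`, `se`,
#'   `n_missing`.
#' @export
locus_set_summary <- function(counts, sets) {
  stopifnot(is.list(sets), length(sets) >= 1L, !is.null(names(sets)))
  rows <- lapply(names(sets), function(d) {
    ids <- unique(sets[[d]])
    found <- ids[ids %in% names(counts)]
    n_missing <- length(ids) - length(found)
    if (n_missing > 0L) {
      message("locus_set_summary: ", d, ": ", n_missing,
              " SNP(s) absent from the count vector, skipped")
    }
    x <- counts[found]
    se <- if (length(x) >= 2L) stats::sd(x) / sqrt(length(x)) else {
      warning("locus set '", d, "' has fewer than 2 resolvable SNPs; SE undefined")
      NA_real_
    }
    data.frame(disease = d, n_loci = length(x),
               mean = if (length(x)) mean(x) else NA_real_,
               se = se, n_missing = n_missing, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Flag diseases whose loci are more pleiotropic than background
#'
#' @param locus_summary data.frame from [locus_set_summary()].
#' @param genome_mean Genome-background mean association count.
#' @return The summary with an added logical `enriched` column
#'   (strict `mean > genome_mean`).
#' @export
enrichment_flag <- function(locus_summary, genome_mean) {
  locus_summary$enriched <- locus_summary$mean > genome_mean
  locus_summary
}
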