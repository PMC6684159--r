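# Summary-statistic ingest, allele orientation, and case-count curation.
#
# Association records are plain data.frames with canonical columns
#   variant, chrom, pos, ref, alt, effect_allele, eaf, n, beta_obs, se_obs,
#   p, phenotype_id
# so they compose with base R and the tidyverse alike.

#' Parse a canonical variant identifier
#'
#' Variant ids follow the `chrom:pos_ref_alt` convention used by the UK
#' Biobank summary-statistic releases (positions 1-based, GRCh37), e.g.
#' `"3:46414943_TACAGTCAGTATCAATTCTGGAAGAATTTCCAG_T"`. The colon-separated
#' `chrom:pos:ref:alt` form is accepted on input and normalised.
#'
#' @param id Character vector of variant ids.
#' @return A data.frame with columns `chrom`, `pos`, `ref`, `alt`, `id`
#'   (the canonical re-formatted id).
#' @export
#' @examples
#' parse_variant_id("3:46414943_TACAGTCAGTATCAATTCTGGAAGAATTTCCAG_T")
parse_variant_id <- function(id) {
  stopifnot(is.character(id), length(id) >= 1L)
  # accept chrom:pos_ref_alt or chrom:pos:ref:alt
  m <- regmatches(id, regexec("^([^:]+):([0-9]+)[_:]([ACGTacgt]+)[_:]([ACGTacgt]+)$", id))
  bad <- vapply(m, length, integer(1)) != 5L
  if (any(bad)) {
    stop("malformed variant id(s): ", paste(utils::head(id[bad], 5), collapse = ", "))
  }
  chrom <- vapply(m, `[[`, character(1), 2L)
  pos <- as.integer(vapply(m, `[[`, character(1), 3L))
  ref <- toupper(vapply(m, `[[`, character(1), 4L))
  alt <- toupper(vapply(m, `[[`, character(1), 5L))
  if (any(pos <= 0L)) stop("variant position must be positive")
  if (any(ref == alt)) stop("ref and alt alleles must differ")
  data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
             id = format_variant_id(chrom, pos, ref, alt),
             stringsAsFactors = FALSE)
}

#' Format a canonical variant identifier
#'
#' @param chrom Chromosome label.
#' @param pos 1-based position.
#' @param ref,alt Allele strings.
#' @return Character vector `chrom:pos_ref_alt`.
#' @export
format_variant_id <- function(chrom, pos, ref, alt) {
  sprintf("%s:%d_%s_%s", chrom, as.integer(pos), ref, alt)
}

#' Default column dialect for summary-statistic files
#'
#' Column-name mapping from the canonical fields to the headers of the
#' source file. The default follows the Neale-lab UK Biobank release
#' (`variant`, `minor_allele`, `minor_AF`, `n_complete_samples`, `beta`,
#' `se`, `pval`), in which the reported frequency belongs to the minor
#' allele; [read_sumstats()] re-expresses it as the effect-allele frequency.
#'
#' @param variant,effect_allele,eaf,n,beta,se,p,phenotype Header names in
#'   the file for each canonical field. `phenotype` may be `NA` when the
#'   file holds a single phenotype (supply `phenotype_id` to
#'   [read_sumstats()] instead).
#' @param freq_is_effect_allele Logical; `TRUE` when the frequency column
#'   already refers to the allele in the effect-allele column, `FALSE`
#'   (Neale convention) when both columns describe the minor allele. Either
#'   way the effect column is taken to be signed with respect to the allele
#'   named in `effect_allele`.
#' @return A list usable as the `dialect` argument of [read_sumstats()].
#' @export
sumstats_dialect <- function(variant = "variant",
                             effect_allele = "minor_allele",
                             eaf = "minor_AF",
                             n = "n_complete_samples",
                             beta = "beta",
                             se = "se",
                             p = "pval",
                             phenotype = "phenotype_id",
                             freq_is_effect_allele = TRUE) {
  list(variant = variant, effect_allele = effect_allele, eaf = eaf,
       n = n, beta = beta, se = se, p = p, phenotype = phenotype,
       freq_is_effect_allele = isTRUE(freq_is_effect_allele))
}

#' Read GWAS summary statistics
#'
#' Reads a tab-separated summary-statistic file, maps its columns through a
#' dialect, validates each row, and returns association records in
#' canonical form. Rows with missing beta or SE are skipped and the skip
#' count reported via [message()]; rows with frequencies outside (0,1) or
#' non-positive SEs are collected and reported as an error.
#'
#' @param path Path to a tab-separated file with a header row.
#' @param dialect Column mapping from [sumstats_dialect()].
#' @param phenotype_id Phenotype id applied to every row when the file has
#'   no phenotype column.
#' @return data.frame of association records (one per retained row) with
#'   attribute `n_skipped` giving the number of NA-dropped rows.
#' @export
read_sumstats <- function(path, dialect = sumstats_dialect(), phenotype_id = NULL) {
  # read everything as character: allele strings like "T" must not be
  # type-converted to logicals
  raw <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                           na.strings = c("NA", "NaN", ""),
                           colClasses = "character")
  needed <- c("variant", "effect_allele", "eaf", "n", "beta", "se", "p")
  for (field in needed) {
    col <- dialect[[field]]
    if (is.null(col) || !col %in% names(raw)) {
      stop("summary-statistic file is missing mandated column '", col,
           "' (field '", field, "')")
    }
  }
  vk <- parse_variant_id(as.character(raw[[dialect$variant]]))
  out <- data.frame(
    variant = vk$id, chrom = vk$chrom, pos = vk$pos, ref = vk$ref, alt = vk$alt,
    effect_allele = toupper(as.character(raw[[dialect$effect_allele]])),
    eaf = as.numeric(raw[[dialect$eaf]]),
    n = as.numeric(raw[[dialect$n]]),
    beta_obs = as.numeric(raw[[dialect$beta]]),
    se_obs = as.numeric(raw[[dialect$se]]),
    p = as.numeric(raw[[dialect$p]]),
    stringsAsFactors = FALSE
  )
  phen_col <- dialect$phenotype
  if (!is.null(phen_col) && !is.na(phen_col) && phen_col %in% names(raw)) {
    out$phenotype_id <- as.character(raw[[phen_col]])
  } else if (!is.null(phenotype_id)) {
    out$phenotype_id <- phenotype_id
  } else {
    stop("no phenotype column '", phen_col, "' in file and no phenotype_id supplied")
  }

  keep <- !(is.na(out$beta_obs) | is.na(out$se_obs))
  n_skipped <- sum(!keep)
  if (n_skipped > 0L) {
    message("read_sumstats: skipped ", n_skipped, " row(s) with missing beta/SE")
  }
  out <- out[keep, , drop = FALSE]

  bad_freq <- which(!is.finite(out$eaf) | out$eaf <= 0 | out$eaf >= 1)
  bad_se <- which(out$se_obs <= 0)
  if (length(bad_freq) || length(bad_se)) {
    stop("invalid rows: ",
         if (length(bad_freq)) paste0(length(bad_freq), " frequency outside (0,1); ") else "",
         if (length(bad_se)) paste0(length(bad_se), " non-positive SE") else "")
  }

  # Neale convention: frequency column refers to the minor allele, which is
  # also the effect allele, so eaf is already correct; dialects for which
  # the frequency belongs to a different allele than the effect column are
  # not representable and must be pre-oriented.
  if (!dialect$freq_is_effect_allele) {
    out$eaf <- 1 - out$eaf
  }
  rownames(out) <- NULL
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Write summary statistics in the canonical dialect
#'
#' @param assocs data.frame of association records.
#' @param path Output path (tab-separated, header row).
#' @return `path`, invisibly.
#' @export
write_sumstats <- function(assocs, path) {
  cols <- c("variant", "effect_allele", "eaf", "n", "beta_obs", "se_obs",
            "p", "phenotype_id")
  stopifnot(all(cols %in% names(assocs)))
  utils::write.table(assocs[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a canonical summary-statistic file back
#'
#' Companion reader for files produced by [write_sumstats()].
#' @param path Path to the file.
#' @return data.frame of association records.
#' @export
read_sumstats_canonical <- function(path) {
  read_sumstats(path, dialect = sumstats_dialect(
    variant = "variant", effect_allele = "effect_allele", eaf = "eaf",
    n = "n", beta = "beta_obs", se = "se_obs", p = "p",
    phenotype = "phenotype_id", freq_is_effect_allele = TRUE))
}

#' Read a phenotype manifest
#'
#' The manifest is tab-separated with columns `phenotype_id`, `name`,
#' `n_cases`, `n_controls`. Prevalence is derived as
#' `n_cases / (n_cases + n_controls)` and never re-estimated downstream.
#'
#' @param path Path to the manifest TSV.
#' @return data.frame with the manifest columns plus `prevalence`.
#' @export
read_pheno_manifest <- function(path) {
  m <- utils::read.delim(path, stringsAsFactors = FALSE)
  needed <- c("phenotype_id", "name", "n_cases", "n_controls")
  missing <- setdiff(needed, names(m))
  if (length(missing)) stop("manifest is missing column(s): ", paste(missing, collapse = ", "))
  m$n_cases <- as.integer(m$n_cases)
  m$n_controls <- as.integer(m$n_controls)
  stopifnot(all(m$n_cases >= 0L), all(m$n_controls >= 0L),
            all(m$n_cases + m$n_controls >= 1L))
  m$prevalence <- m$n_cases / (m$n_cases + m$n_controls)
  m
}

#' Orient association records to a target allele
#'
#' Effects must be signed with respect to one designated allele (here the
#' edited/deletion allele) before any cross-phenotype comparison. If the
#' record's effect allele already equals the target it is returned
#' unchanged; if the target is the record's other allele, the beta is
#' negated and the frequency complemented. SE, p, and n are untouched, so
#' the operation is an involution.
#'
#' @param assocs data.frame of association records.
#' @param target Target allele string.
#' @return data.frame with every record oriented to `target`.
#' @export
orient_to_target_allele <- function(assocs, target) {
  target <- toupper(target)
  other <- ifelse(assocs$effect_allele == assocs$ref, assocs$alt, assocs$ref)
  mismatch <- assocs$effect_allele != target & other != target
  if (any(mismatch)) {
    stop("target allele '", target, "' matches neither allele for ",
         sum(mismatch), " record(s), e.g. variant ",
         assocs$variant[which(mismatch)[1]])
  }
  flip <- assocs$effect_allele != target
  assocs$beta_obs[flip] <- -assocs$beta_obs[flip]
  assocs$eaf[flip] <- 1 - assocs$eaf[flip]
  assocs$effect_allele[flip] <- target
  assocs
}

#' Filter associations to curated phenotypes by case count
#'
#' Retains associations whose phenotype has at least `min_cases` cases in
#' the manifest (boundary inclusive), preserving input order.
#'
#' @param assocs data.frame of association records.
#' @param metas Phenotype manifest from [read_pheno_manifest()].
#' @param min_cases Minimum case count (default 1000).
#' @return Filtered data.frame.
#' @export
filter_curated <- function(assocs, metas, min_cases = 1000) {
  idx <- match(assocs$phenotype_id, metas$phenotype_id)
  if (anyNA(idx)) {
    stop("no manifest entry for phenotype(s): ",
         paste(unique(assocs$phenotype_id[is.na(idx)]), collapse = ", "))
  }
  keep <- metas$n_cases[idx] >= min_cases
  out <- assocs[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
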