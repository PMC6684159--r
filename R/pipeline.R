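# Orchestration of the full audit: ingest -> orient -> filter ->
# transform -> mixture -> enrichment -> report bundle, plus thin wrappers
# for the contingency and pleiotropy analyses and the generators. All
# outputs are plain TSV/JSON carrying the config hash and seed, so
# re-running with an identical config reproduces identical analytical
# payloads.

#' Audit run configuration
#'
#' @param sumstats Path to the summary-statistic TSV.
#' @param manifest Path to the phenotype manifest TSV.
#' @param target_allele Allele the audit signs all effects by (the edited
#'   allele).
#' @param dialect Column dialect for the summary-statistic file.
#' @param min_cases Curation threshold on phenotype case counts.
#' @param fdr_q FDR threshold for labelling.
#' @param n_restarts Mixture optimiser restarts.
#' @param n_boot Bootstrap replicates (0 disables bootstrap inference).
#' @param tol Mixture convergence tolerance.
#' @param seed Seed for every stochastic stage of the run.
#' @param out_dir Output directory for the report bundle.
#' @return An `audit_config` list.
#' @export
audit_config <- function(sumstats, manifest, target_allele,
                         dialect = sumstats_dialect(),
                         min_cases = 1000L, fdr_q = 0.05,
                         n_restarts = 20L, n_boot = 1000L, tol = 1e-8,
                         seed = 1L, out_dir = "audit_out") {
  stopifnot(min_cases >= 0, fdr_q > 0, fdr_q < 1, n_restarts >= 1,
            n_boot >= 0, tol > 0)
  structure(list(sumstats = sumstats, manifest = manifest,
                 target_allele = toupper(target_allele), dialect = dialect,
                 min_cases = as.integer(min_cases), fdr_q = fdr_q,
                 n_restarts = as.integer(n_restarts),
                 n_boot = as.integer(n_boot), tol = tol, seed = seed,
                 out_dir = out_dir),
            class = "audit_config")
}

# stable hash of the analytical configuration (md5 of its canonical JSON);
# file-system locations are excluded so relocated copies of the same
# analysis hash identically
.config_hash <- function(config) {
  cfg <- config[setdiff(names(config), c("out_dir", "sumstats", "manifest"))]
  cfg$dialect <- unlist(cfg$dialect)
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA), tmp)
  unname(tools::md5sum(tmp))
}

.write_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full pleiotropy audit
#'
#' Reads and curates the summary statistics, orients every effect to the
#' target allele, transforms to the odds-ratio scale, fits the
#' three-component Z-score mixture with bootstrap inference, and computes
#' the enrichment report. Writes `or_table.tsv`, `mixture.json`,
#' `posterior.tsv`, `enrichment.json`, `qq.tsv`, and `run_info.json`
#' under `config$out_dir`. Deterministic given the config seed.
#'
#' @param config An [audit_config()].
#' @return Invisibly, a list with `effects`, `mixture_fit`, `bootstrap`,
#'   `enrichment`, `expected_affected`, and `run_info`.
#' @export
run_audit <- function(config) {
  stopifnot(inherits(config, "audit_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("audit stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  assocs <- stage("ingest", read_sumstats(config$sumstats, config$dialect))
  metas <- stage("ingest", read_pheno_manifest(config$manifest))
  message("run_audit: ", nrow(assocs), " associations ingested")
  assocs <- stage("orient", orient_to_target_allele(assocs, config$target_allele))
  assocs <- stage("filter", filter_curated(assocs, metas, config$min_cases))
  message("run_audit: ", nrow(assocs), " associations after curation (min_cases = ",
          config$min_cases, ")")
  effects <- stage("transform", batch_transform(assocs, metas))
  fit <- stage("mixture", fit_mixture(effects$z, n_restarts = config$n_restarts,
                                      seed = config$seed, tol = config$tol))
  boot <- if (config$n_boot >= 100L) {
    stage("bootstrap", bootstrap_inference(effects$z, fit,
                                           n_boot = config$n_boot,
                                           seed = config$seed))
  } else NULL
  enr <- stage("enrichment", enrichment_report(effects, fdr_q = config$fdr_q))
  exp_aff <- expected_affected(fit$params, nrow(effects))

  run_info <- list(config_hash = .config_hash(config), seed = config$seed,
                   n_ingested = nrow(assocs), n_analyzed = nrow(effects),
                   min_cases = config$min_cases, fdr_q = config$fdr_q)

  .write_tsv(effects, file.path(config$out_dir, "or_table.tsv"))
  .write_tsv(enr$per_phenotype, file.path(config$out_dir, "fdr_table.tsv"))
  .write_tsv(enr$qq, file.path(config$out_dir, "qq.tsv"))
  post <- data.frame(phenotype_id = effects$phenotype_id,
                     p_protective = fit$posterior[, 1],
                     p_null = fit$posterior[, 2],
                     p_harmful = fit$posterior[, 3])
  .write_tsv(post, file.path(config$out_dir, "posterior.tsv"))
  .write_json(c(run_info,
                list(params = unclass(fit$params), loglik = fit$loglik,
                     n = fit$n, n_restarts = fit$n_restarts,
                     converged = fit$converged,
                     boot_se = if (!is.null(boot)) as.list(boot$boot_se),
                     boot_p = if (!is.null(boot)) as.list(boot$boot_p),
                     n_boot = if (!is.null(boot)) boot$n_boot,
                     expected_affected = exp_aff)),
              file.path(config$out_dir, "mixture.json"))
  .write_json(c(run_info,
                list(n_harmful = enr$n_harmful, n_protective = enr$n_protective,
                     n_zero = enr$n_zero, wilcoxon_p = enr$wilcoxon_p,
                     fdr_hits = enr$fdr_hits)),
              file.path(config$out_dir, "enrichment.json"))

  invisible(list(effects = effects, mixture_fit = fit, bootstrap = boot,
                 enrichment = enr, expected_affected = exp_aff,
                 run_info = run_info))
}

#' Run the contingency-table odds-ratio analysis
#'
#' Reads genotype counts from a JSON file (`{"cases": [a,b,c],
#' "controls": [d,e,f]}`, genotype order wildtype/het/deletion-homozygote)
#' or accepts a [genotype_table()] directly, fits the allele-dose logistic
#' regression, and optionally writes a JSON report.
#'
#' @param table Path to a JSON count file, or a `genotype_table`.
#' @param out Optional output path for the JSON report.
#' @return The [allelic_logistic_or()] result (without the glm object in
#'   the written report).
#' @export
run_contingency <- function(table, out = NULL) {
  if (is.character(table)) {
    raw <- jsonlite::read_json(table, simplifyVector = TRUE)
    table <- genotype_table(raw$cases, raw$controls)
  }
  res <- allelic_logistic_or(table)
  if (!is.null(out)) {
    .write_json(res[c("or", "logor", "se_logor", "p", "ci_lower", "ci_upper")],
                out)
  }
  res
}

#' Run the pleiotropy-count analysis
#'
#' Counts associations per SNP at the threshold, summarises the genome
#' background (optionally MAF-stratified) and any locus sets, and flags
#' diseases whose loci exceed the background mean.
#'
#' @param m A [pvalue_matrix()], or path to a long-format TSV with
#'   columns `snp`, `maf`, `phenotype`, `p`.
#' @param locus_sets Optional named list of SNP-id vectors (or path to a
#'   TSV with columns `disease`, `snp`).
#' @param threshold Association p-value cutoff (default 5e-4).
#' @param maf_min Optional MAF bound for the background stratum.
#' @param out Optional output path for the JSON summary.
#' @return List with `counts`, `background`, and (when sets are given)
#'   `per_disease` including enrichment flags.
#' @export
run_pleiotropy <- function(m, locus_sets = NULL, threshold = 5e-4,
                           maf_min = 0.3, out = NULL) {
  if (is.character(m)) {
    long <- utils::read.delim(m, stringsAsFactors = FALSE)
    stopifnot(all(c("snp", "maf", "phenotype", "p") %in% names(long)))
    snp_ids <- unique(long$snp)
    phen_ids <- unique(long$phenotype)
    p <- matrix(NA_real_, length(snp_ids), length(phen_ids),
                dimnames = list(snp_ids, phen_ids))
    p[cbind(match(long$snp, snp_ids), match(long$phenotype, phen_ids))] <- long$p
    maf <- long$maf[match(snp_ids, long$snp)]
    m <- pvalue_matrix(p, snp_ids, maf, phen_ids)
  }
  if (is.character(locus_sets)) {
    ls_df <- utils::read.delim(locus_sets, stringsAsFactors = FALSE)
    stopifnot(all(c("disease", "snp") %in% names(ls_df)))
    locus_sets <- split(ls_df$snp, ls_df$disease)
  }
  counts <- count_associations(m, threshold = threshold)
  bg <- background_summary(counts, m$maf, maf_min = maf_min)
  res <- list(counts = counts, background = bg)
  if (!is.null(locus_sets)) {
    res$per_disease <- enrichment_flag(locus_set_summary(counts, locus_sets),
                                       bg$mean)
  }
  if (!is.null(out)) {
    .write_json(list(background = bg,
                     per_disease = res$per_disease,
                     threshold = threshold, maf_min = maf_min), out)
  }
  res
}

#' Generate and write synthetic audit inputs
#'
#' Runs [gen_phenotype_panel()] and writes the summary statistics and
#' manifest in the dialects [read_sumstats()] reads, alongside a
#' ground-truth JSON for recovery checks.
#'
#' @param spec A [panel_spec()].
#' @param out_dir Output directory.
#' @return Invisibly, the generated panel list with a `paths` element.
#' @export
run_simulate <- function(spec, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  panel <- gen_phenotype_panel(spec)
  paths <- list(sumstats = file.path(out_dir, "sumstats.tsv"),
                manifest = file.path(out_dir, "manifest.tsv"),
                truth = file.path(out_dir, "truth.json"))
  write_sumstats(panel$assocs, paths$sumstats)
  .write_tsv(panel$metas[, c("phenotype_id", "name", "n_cases", "n_controls")],
             paths$manifest)
  .write_json(list(spec = c(unclass(spec)[c("n_phenotypes", "prevalence_range",
                                            "eaf", "n_samples", "seed")],
                            list(mixture = unclass(spec$mixture))),
                   truth = panel$truth), paths$truth)
  panel$paths <- paths
  invisible(panel)
}
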