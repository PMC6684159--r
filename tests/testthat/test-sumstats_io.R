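test_that("variant ids round-trip through parse and format", {
  ids <- c("3:46414943_TACAGTCAGTATCAATTCTGGAAGAATTTCCAG_T",
           "1:1000_A_G", "X:55_AT_A")
  vk <- parse_variant_id(ids)
  expect_equal(vk$id, ids)
  expect_equal(format_variant_id(vk$chrom, vk$pos, vk$ref, vk$alt), ids)
  # colon-separated form normalises to the canonical underscore form
  expect_equal(parse_variant_id("1:1000:A:G")$id, "1:1000_A_G")
  expect_error(parse_variant_id("1:1000_A"), "malformed")
  expect_error(parse_variant_id("1:1000_A_A"), "differ")
})

test_that("read_sumstats ingests well-formed rows and skips NA beta rows", {
  f <- withr::local_tempfile(fileext = ".tsv")
  write_neale_fixture(f, n = 3)
  a <- read_sumstats(f)
  expect_equal(nrow(a), 3L)
  expect_equal(attr(a, "n_skipped"), 0L)
  expect_equal(a$eaf, rep(0.092, 3))
  expect_equal(a$effect_allele, rep("T", 3))

  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_neale_fixture(f2, n = 3, na_beta_rows = 2L)
  expect_message(a2 <- read_sumstats(f2), "skipped 1 row")
  expect_equal(nrow(a2), 2L)
  expect_equal(attr(a2, "n_skipped"), 1L)
})

test_that("read_sumstats reports missing columns and bad frequencies", {
  f <- withr::local_tempfile(fileext = ".tsv")
  df <- write_neale_fixture(f, n = 2)
  df$minor_AF <- NULL
  utils::write.table(df, f, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_sumstats(f), "minor_AF")

  f2 <- withr::local_tempfile(fileext = ".tsv")
  df2 <- write_neale_fixture(f2, n = 2)
  df2$minor_AF[1] <- 1.7
  utils::write.table(df2, f2, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_sumstats(f2), "frequency")
})

test_that("write then read reproduces all retained fields", {
  f <- withr::local_tempfile(fileext = ".tsv")
  write_neale_fixture(f, n = 5, na_beta_rows = 3L)
  a <- suppressMessages(read_sumstats(f))
  out <- withr::local_tempfile(fileext = ".tsv")
  write_sumstats(a, out)
  b <- read_sumstats_canonical(out)
  for (col in c("variant", "effect_allele", "eaf", "n", "beta_obs",
                "se_obs", "p", "phenotype_id")) {
    expect_equal(b[[col]], a[[col]], info = col)
  }
  # second round trip is exact (idempotence on retained records)
  out2 <- withr::local_tempfile(fileext = ".tsv")
  write_sumstats(b, out2)
  expect_identical(readLines(out), readLines(out2))
})

test_that("orienting to the current effect allele is the identity", {
  f <- withr::local_tempfile(fileext = ".tsv")
  write_neale_fixture(f, n = 3)
  a <- read_sumstats(f)
  expect_identical(orient_to_target_allele(a, "T"), a)
})

test_that("orienting to the other allele flips sign and frequency, and is an involution", {
  f <- withr::local_tempfile(fileext = ".tsv")
  write_neale_fixture(f, n = 4)
  a <- read_sumstats(f)
  other <- a$ref[1]  # effect allele is the alt in the fixture
  b <- orient_to_target_allele(a, other)
  expect_equal(b$beta_obs, -a$beta_obs)
  expect_equal(b$eaf, 1 - a$eaf)
  expect_equal(b$effect_allele, rep(other, 4))
  expect_equal(b$se_obs, a$se_obs)
  expect_equal(b$p, a$p)
  expect_equal(b$n, a$n)
  # orienting twice returns the original record (floating-point complement
  # of eaf is the only inexact field)
  back <- orient_to_target_allele(b, "T")
  expect_identical(back$beta_obs, a$beta_obs)
  expect_identical(back$effect_allele, a$effect_allele)
  expect_equal(back$eaf, a$eaf, tolerance = 1e-14)
  expect_error(orient_to_target_allele(a, "GGG"), "neither allele")
})

test_that("curation keeps phenotypes with at least min_cases cases", {
  f <- withr::local_tempfile(fileext = ".tsv")
  write_neale_fixture(f, n = 3)
  a <- read_sumstats(f)
  metas <- manifest_fixture(a$phenotype_id, c(999L, 1000L, 5000L))
  kept <- filter_curated(a, metas, min_cases = 1000)
  expect_equal(kept$phenotype_id, c("pheno_002", "pheno_003"))
  expect_equal(nrow(filter_curated(a, metas, min_cases = 0)), 3L)
  expect_error(filter_curated(a, metas[-1, ], 1000), "pheno_001")
})

test_that("curation matches a brute-force filter and is monotone in min_cases", {
  n <- 40
  f <- withr::local_tempfile(fileext = ".tsv")
  write_neale_fixture(f, n = n)
  a <- read_sumstats(f)
  cases <- with_seed(11, sample(100:10000, n))
  metas <- manifest_fixture(a$phenotype_id, cases)
  prev_n <- Inf
  for (mc in c(0, 500, 1000, 2000, 5000, 20000)) {
    kept <- filter_curated(a, metas, min_cases = mc)
    brute <- a$phenotype_id[cases >= mc]
    expect_equal(kept$phenotype_id, brute)
    expect_lte(nrow(kept), prev_n)
    prev_n <- nrow(kept)
  }
})

test_that("the phenotype manifest derives prevalence from counts", {
  f <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(
    data.frame(phenotype_id = "p1", name = "toy", n_cases = 25, n_controls = 75),
    f, sep = "\t", quote = FALSE, row.names = FALSE)
  m <- read_pheno_manifest(f)
  expect_equal(m$prevalence, 0.25)
  f2 <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(data.frame(phenotype_id = "p1", name = "toy", n_cases = 5),
                     f2, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_pheno_manifest(f2), "n_controls")
})
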