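test_that("delimited files parse, validate, and report dropped rows", {
  path <- withr::local_tempfile(fileext = ".tsv")
  df <- data.frame(
    variant_id = c("rs1", "rs2", "rs3"), chromosome = "1",
    position = c(100L, 200L, 300L), effect_allele = c("A", "C", "G"),
    other_allele = c("G", "T", "A"), eaf = c(0.2, 0.3, 0.4),
    beta = c(0.1, -0.2, 0.05), se = c(0.02, 0.03, 0.01),
    pvalue = c(1e-6, 0.5, 0.01), n = 5000L
  )
  readr::write_tsv(df, path)
  ss <- read_summary_stats(path, trait_label = "t", quiet = TRUE)
  expect_s3_class(ss, "summary_stats")
  expect_equal(nrow(ss), 3)
  expect_equal(ss$beta, df$beta)

  # invariant enforcement: se = 0 row dropped and counted
  df_bad <- df
  df_bad$se[2] <- 0
  readr::write_tsv(df_bad, path)
  ss2 <- NULL
  expect_message(ss2 <- read_summary_stats(path, trait_label = "t"),
                 "dropped 1")
  expect_equal(nrow(ss2), 2)
  expect_equal(dropped_rows(ss2)$reason, "nonpositive_se")

  # all rows invalid -> input error; missing column -> configuration error
  df_bad$se <- 0
  readr::write_tsv(df_bad, path)
  expect_error(read_summary_stats(path, trait_label = "t"),
               class = "mrmediate_input_error")
  readr::write_tsv(df[, -4], path)
  expect_error(read_summary_stats(path, trait_label = "t"),
               class = "mrmediate_config_error")
})

test_that("GWAS-Catalog-style headers and comma files are supported", {
  path <- withr::local_tempfile(fileext = ".csv")
  df <- data.frame(
    variant_id = "rs1", chromosome = "2", base_pair_location = 1234L,
    effect_allele = "A", other_allele = "G",
    effect_allele_frequency = 0.25, beta = 0.07, standard_error = 0.01,
    p_value = 1e-12, n = 20000L
  )
  readr::write_csv(df, path)
  ss <- read_summary_stats(path, trait_label = "t",
                           dialect = dialect_gwas_catalog(), quiet = TRUE)
  expect_equal(ss$position, 1234L)
  expect_equal(ss$pvalue, 1e-12)
})

test_that("write/read round-trip preserves every field", {
  sim <- simulate_triplet(sim_config(n_snps = 10, n_mediator_snps = 0,
                                     seed = 5))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_summary_stats(sim$exposure, path)
  back <- read_summary_stats(path, trait_label = trait_label(sim$exposure),
                             quiet = TRUE)
  expect_equal(as.data.frame(back), as.data.frame(sim$exposure))
})

test_that("harmonization keeps, flips and drops variants by the allele rules", {
  mk <- function(id, ea, oa, eaf, beta, label) {
    summary_stats(
      data.frame(variant_id = id, chromosome = "1",
                 position = seq_along(id) * 1000L,
                 effect_allele = ea, other_allele = oa, eaf = eaf,
                 beta = beta, se = 0.02, pvalue = 1e-6, n = 10000L),
      trait_label = label, quiet = TRUE
    )
  }
  exp <- mk(c("rs1", "rs2", "rs3", "rs4"), c("A", "A", "A", "A"),
            c("G", "G", "T", "G"), c(0.3, 0.3, 0.5, 0.3),
            c(0.2, 0.2, 0.2, 0.2), "exp")
  out <- mk(c("rs1", "rs2", "rs3", "rs4"), c("A", "G", "A", "C"),
            c("G", "A", "T", "T"), c(0.3, 0.7, 0.5, 0.3),
            c(0.1, 0.1, 0.1, 0.1), "out")
  h <- harmonize(exp, out)
  expect_equal(h$variant_id, c("rs1", "rs2"))
  expect_equal(h$beta_outcome, c(0.1, -0.1))  # swap negates
  d <- dropped_rows(h)
  expect_equal(d$reason[d$variant_id == "rs3"], "palindromic_ambiguous")
  expect_equal(d$reason[d$variant_id == "rs4"], "allele_mismatch")
  # kept + dropped partition the intersection
  expect_setequal(c(h$variant_id, d$variant_id),
                  intersect(exp$variant_id, out$variant_id))
  # empty intersection errors with both labels
  out2 <- mk("rs9", "A", "G", 0.3, 0.1, "out")
  expect_error(harmonize(exp, out2), "exp.*out", class = "mrmediate_input_error")
})

test_that("palindromic variants need informative, concordant frequencies", {
  mk1 <- function(eaf_exp, eaf_out) {
    e <- summary_stats(
      data.frame(variant_id = "rs1", chromosome = "1", position = 1L,
                 effect_allele = "C", other_allele = "G", eaf = eaf_exp,
                 beta = 0.2, se = 0.02, pvalue = 1e-6, n = 1000L),
      trait_label = "e", quiet = TRUE)
    o <- summary_stats(
      data.frame(variant_id = "rs1", chromosome = "1", position = 1L,
                 effect_allele = "C", other_allele = "G", eaf = eaf_out,
                 beta = 0.1, se = 0.02, pvalue = 1e-6, n = 1000L),
      trait_label = "o", quiet = TRUE)
    harmonize(e, o)
  }
  expect_equal(nrow(mk1(0.2, 0.25)), 1)          # clear, concordant
  expect_equal(nrow(mk1(0.2, 0.8)), 0)           # discordant orientation
  expect_equal(nrow(mk1(0.45, 0.45)), 0)         # inside the ambiguous zone
  expect_equal(nrow(mk1(NA, 0.2)), 0)            # missing frequency
  expect_equal(dropped_rows(mk1(0.45, 0.45))$reason, "palindromic_ambiguous")
})

test_that("harmonization is involutive under outcome allele relabelling", {
  for (seed in 1:5) {
    exp <- make_ss(8, seed = seed, label = "exp")
    out <- make_ss(8, seed = seed + 100, label = "out")
    # same variants/alleles as the exposure, fresh effects
    out$effect_allele <- exp$effect_allele
    out$other_allele <- exp$other_allele
    h1 <- harmonize(exp, out)
    # relabel the outcome's effect allele: swap alleles, negate beta,
    # complement eaf -- a self-consistent rewriting of the same data
    flipped <- as.data.frame(out)
    flipped[, c("effect_allele", "other_allele")] <-
      flipped[, c("other_allele", "effect_allele")]
    flipped$beta <- -flipped$beta
    flipped$eaf <- 1 - flipped$eaf
    out2 <- summary_stats(flipped, trait_label = "out", quiet = TRUE)
    h2 <- harmonize(exp, out2)
    expect_equal(as.data.frame(h1), as.data.frame(h2))
  }
})
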