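test_that("allele-frequency concordance flags departures beyond af_delta", {
  panel <- depalindrome(make_panel(n = 100L, m = 50L, seed = 31L))
  tab <- harmonize_study(make_scan(panel), panel)$table
  clean <- af_concordance(tab, panel, af_delta = 0.2)
  expect_true(all(clean$checked))
  expect_false(any(clean$flag))

  r <- tab$records
  r$eaf[1] <- min(r$eaf[1] + 0.35, 1)   # push one SNP out of tolerance
  r$eaf[2] <- NA_real_                  # unchecked, never flagged
  bad <- af_concordance(sumstats_table(r, tab$metadata), panel, 0.2)
  expect_true(bad$flag[1])
  expect_false(bad$checked[2])
  expect_false(bad$flag[2])
  expect_equal(sum(bad$flag), 1L)

  # jitter within +-0.05 never crosses a 0.2 threshold
  r2 <- tab$records
  set.seed(1)
  r2$eaf <- pmin(pmax(r2$eaf + runif(nrow(r2), -0.05, 0.05), 0), 1)
  expect_equal(sum(af_concordance(sumstats_table(r2, tab$metadata),
                                  panel, 0.2)$flag), 0L)
})

test_that("p/Z concordance flags inconsistent reported p-values", {
  rec <- data.frame(snp_id = c("a", "b", "c", "d"), chrom = "1",
                    pos = 1:4 * 10L, ea = "A", oa = "G", eaf = 0.5,
                    beta = c(0.1, 0.1, 0, 0.2), se = c(0.05, 0.05, 0.05, NA),
                    p = c(2 * pnorm(2, lower.tail = FALSE), 1e-8, 1, 0.5),
                    z = NA_real_, n = 100L, stringsAsFactors = FALSE)
  flags <- pz_concordance(sumstats_table(rec, test_meta()), logp_delta = 1)
  expect_false(flags$flag[1])  # consistent: p matches 2(1 - Phi(2))
  expect_true(flags$flag[2])   # 1e-8 vs 0.0455: ~6.3 decades apart
  expect_false(flags$flag[3])  # beta 0 -> p_computed 1, reported 1
  expect_false(flags$checked[4])  # missing se: unchecked
})

test_that("effect-size skewness matches the moment definition", {
  tab <- function(b) sumstats_table(
    data.frame(snp_id = sprintf("s%d", seq_along(b)), chrom = "1",
               pos = 10L * seq_along(b), ea = "A", oa = "G", eaf = 0.5,
               beta = b, se = 0.1, p = 0.5, z = 0, n = 10L,
               stringsAsFactors = FALSE), test_meta())
  sym <- effect_distribution_stats(tab(rep(c(-2, -1, 0, 1, 2), 2)))
  expect_equal(sym$skewness, 0)
  expect_true(sym$symmetric)
  asym <- effect_distribution_stats(tab(c(rep(0, 8), 10, 10)))
  # m3/m2^1.5 for {0 x 8, 10 x 2}: frozen by direct moment computation
  expect_equal(asym$skewness, 1.5, tolerance = 1e-12)
  expect_false(asym$symmetric)
  short <- effect_distribution_stats(tab(c(-1, 0, 1, 2, 3, -2, 1, 0, 1)))
  expect_equal(short$status, "insufficient_data")
  # near-normal betas at scale: skewness concentrates near 0
  set.seed(2)
  big <- effect_distribution_stats(tab(rnorm(10000, 0, 0.1)))
  expect_lt(abs(big$skewness), 0.1)
})

test_that("genomic control lambda follows the chi-square median definition", {
  tab <- function(z) sumstats_table(
    data.frame(snp_id = sprintf("s%d", seq_along(z)), chrom = "1",
               pos = 10L * seq_along(z), ea = "A", oa = "G", eaf = 0.5,
               beta = NA_real_, se = NA_real_, p = NA_real_, z = z,
               n = 100L, stringsAsFactors = FALSE), test_meta())
  expect_equal(genomic_control_lambda(tab(rep(sqrt(0.4549364), 12) *
                                            rep(c(-1, 1), 6))), 1,
               tolerance = 1e-6)
  # z in {1,2,3} repeated: median z^2 = 4 -> lambda = 8.7924 (4/0.4549364)
  expect_equal(genomic_control_lambda(tab(rep(c(1, 2, 3), 4))), 8.792433,
               tolerance = 1e-4)
  expect_warning(lam <- genomic_control_lambda(tab(c(1, 2))), "fewer than 10")
  expect_true(is.na(lam))

  # invariance under sign flip, quadratic under scaling
  set.seed(5)
  z <- rnorm(1000)
  expect_equal(genomic_control_lambda(tab(-z)), genomic_control_lambda(tab(z)))
  expect_equal(genomic_control_lambda(tab(3 * z)),
               9 * genomic_control_lambda(tab(z)), tolerance = 1e-12)
  # null z-scores at m = 10000: lambda concentrates near 1
  set.seed(6)
  expect_lt(abs(genomic_control_lambda(tab(rnorm(10000))) - 1), 0.05)
})

test_that("implied trait variance recovers the phenotype scale", {
  tab <- sumstats_table(
    data.frame(snp_id = sprintf("s%d", 1:12), chrom = "1", pos = 10L * (1:12),
               ea = "A", oa = "G", eaf = 0.5, beta = 0.01, se = 0.1,
               p = 0.9, z = 0.1, n = 100L, stringsAsFactors = FALSE),
    test_meta())
  expect_equal(estimate_trait_variance(tab), 0.5)  # 0.1^2 * 100 * 2*0.25

  # recovery from a simulated scan of a variance-1 phenotype
  panel <- make_panel(n = 2000L, m = 500L, seed = 33L)
  cfg <- sim_config(2000L, 500L, h2 = 0.5, n_causal = 50L, seed = 33L)
  ph <- simulate_phenotype(panel, cfg)
  scan <- gwas_scan(panel, ph$phenotype)
  v <- estimate_trait_variance(scan)
  expect_gt(v, 0.9); expect_lt(v, 1.1)
})

test_that("the upload verdict flips strictly above the outlier threshold", {
  panel <- depalindrome(make_panel(n = 500L, m = 1000L, seed = 41L,
                                   maf_range = c(0.05, 0.3)))
  tab <- harmonize_study(make_scan(panel, h2 = 0.3), panel)$table
  clean <- qc_verdict(tab, panel)
  expect_equal(clean$verdict, "recommended")
  expect_equal(clean$outlier_fraction, 0)

  # all eafs are below 0.35 here, so every frequency flip is a flagged outlier
  frac_verdict <- function(frac) {
    bad <- corrupt_sumstats(tab, "af_flip", frac, seed = 9L)
    qc_verdict(bad, panel)
  }
  at5 <- frac_verdict(0.05)
  expect_equal(at5$outlier_fraction, 0.05)
  expect_equal(at5$verdict, "recommended")      # 5.0 % is not > 5 %
  above <- frac_verdict(0.055)
  expect_equal(above$outlier_fraction, 0.055)
  expect_equal(above$verdict, "not_recommended")
  at10 <- frac_verdict(0.10)
  expect_equal(at10$outlier_fraction, 0.10, tolerance = 1e-12)
  expect_equal(at10$verdict, "not_recommended")
})

test_that("an asymmetric effect-size distribution alone blocks the verdict", {
  panel <- depalindrome(make_panel(n = 300L, m = 200L, seed = 44L))
  tab <- harmonize_study(make_scan(panel), panel)$table
  r <- tab$records
  r$beta <- abs(r$beta) * 3        # heavily right-skewed, frequencies intact
  r$p <- 2 * pnorm(abs(r$beta / r$se), lower.tail = FALSE)
  r$z <- r$beta / r$se
  skewed <- qc_verdict(sumstats_table(r, tab$metadata), panel)
  expect_lte(skewed$outlier_fraction, 0.05)
  expect_gt(abs(skewed$effect_skewness), 0.5)
  expect_equal(skewed$verdict, "not_recommended")
})

test_that("outlier fraction is invariant to record order", {
  panel <- depalindrome(make_panel(n = 200L, m = 100L, seed = 47L,
                                   maf_range = c(0.05, 0.3)))
  tab <- harmonize_study(make_scan(panel), panel)$table
  bad <- corrupt_sumstats(tab, "af_flip", 0.08, seed = 3L)
  perm <- with_seed(10L, sample(nrow(bad$records)))
  shuffled <- sumstats_table(bad$records[perm, ], bad$metadata)
  expect_equal(qc_verdict(shuffled, panel)$outlier_fraction,
               qc_verdict(bad, panel)$outlier_fraction)
})

test_that("null simulated studies pass QC at default thresholds", {
  panel <- depalindrome(make_panel(n = 300L, m = 400L, seed = 50L))
  verdicts <- vapply(1:20, function(s) {
    cfg <- sim_config(300L, 400L, h2 = 0, n_causal = 0L, seed = 100L + s)
    ph <- simulate_phenotype(panel, cfg)
    tab <- harmonize_study(gwas_scan(panel, ph$phenotype), panel)$table
    qc_verdict(tab, panel)$verdict
  }, character(1))
  expect_true(all(verdicts == "recommended"))
})
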