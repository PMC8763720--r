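# The reference orientation takes the panel alt allele as effect allele; the
# alignment cases below cover swap, strand, palindromic and mismatch paths.

test_that("align_alleles classifies the non-ambiguous orientations", {
  # ref pair (ref = G, alt = A)
  exact <- align_alleles("A", "G", "G", "A", 0.3, 0.3)
  expect_equal(exact$code, "EXACT")
  expect_false(exact$sign_flip)

  swap <- align_alleles("G", "A", "G", "A", 0.7, 0.3)
  expect_equal(swap$code, "SWAP")
  expect_true(swap$sign_flip)
  expect_true(swap$eaf_complemented)

  # study reported on the opposite strand: T/C complements to A/G
  strand <- align_alleles("T", "C", "G", "A", 0.3, 0.3)
  expect_equal(strand$code, "STRAND")
  expect_false(strand$sign_flip)

  strand_swap <- align_alleles("C", "T", "G", "A", 0.7, 0.3)
  expect_equal(strand_swap$code, "STRAND_SWAP")
  expect_true(strand_swap$sign_flip)

  mism <- align_alleles("A", "C", "G", "A", 0.3, 0.3)
  expect_equal(mism$code, "MISMATCH")
})

test_that("palindromic pairs resolve by frequency below the MAF threshold", {
  # Brute-force oracle: among the two orientations (as-is / swapped), pick the
  # one minimizing |eaf - ref_af|, allowed only when both MAFs < threshold.
  brute <- function(eaf, ref_af, thr = 0.4) {
    if (min(eaf, 1 - eaf) >= thr || min(ref_af, 1 - ref_af) >= thr)
      return("drop")
    if (abs(1 - eaf - ref_af) < abs(eaf - ref_af)) "swapped" else "as_is"
  }
  cases <- expand.grid(eaf = c(0.05, 0.10, 0.35, 0.45, 0.90),
                       ref_af = c(0.08, 0.12, 0.48, 0.88))
  for (i in seq_len(nrow(cases))) {
    out <- align_alleles("A", "T", "T", "A", cases$eaf[i], cases$ref_af[i])
    want <- brute(cases$eaf[i], cases$ref_af[i])
    if (want == "drop") {
      expect_equal(out$code, "AMBIGUOUS_DROPPED")
    } else {
      expect_equal(out$code, "AMBIGUOUS_RESOLVED")
      expect_equal(out$sign_flip, want == "swapped")
    }
  }
  # spec-style case: ea=A, oa=T, eaf 0.10, ref alt=A at 0.12 -> as-is
  res <- align_alleles("A", "T", "T", "A", 0.10, 0.12)
  expect_equal(res$code, "AMBIGUOUS_RESOLVED")
  expect_false(res$sign_flip)
  # palindromic with missing study frequency cannot be resolved
  expect_equal(align_alleles("C", "G", "G", "C", NA_real_, 0.2)$code,
               "AMBIGUOUS_DROPPED")
})

test_that("z_from_p inverts the two-sided normal tail", {
  expect_equal(z_from_p(1, 1), 0)
  expect_equal(z_from_p(1, -3), 0)
  # independent oracle: root of 2*(1 - Phi(z)) = p
  invert <- function(p) uniroot(function(z)
    2 * pnorm(z, lower.tail = FALSE) - p, c(0, 40), tol = 1e-12)$root
  for (p in c(0.5, 0.05, 0.0455, 1e-4, 1e-10)) {
    expect_equal(z_from_p(p, 1), invert(p), tolerance = 1e-8)
    expect_equal(z_from_p(p, -2), -invert(p), tolerance = 1e-8)
  }
  expect_equal(z_from_p(0.05, 1), 1.959964, tolerance = 1e-6)
  expect_equal(z_from_p(0.0455, -1), -2.000, tolerance = 1e-3)
  expect_error(z_from_p(0, 1), "p-values")
  expect_error(z_from_p(1.2, 1), "p-values")
  expect_warning(z_from_p(1e-320, 1), "clamped")
})

test_that("recover_se reproduces the standard error from beta and p", {
  expect_equal(as.numeric(recover_se(0.1, 0.0455)), 0.05, tolerance = 1e-3)
  expect_equal(as.numeric(recover_se(-0.3, 0.0455)), 0.15, tolerance = 1e-3)
  degenerate <- recover_se(0.1, 1)
  expect_true(is.na(as.numeric(degenerate)))
  expect_equal(attr(degenerate, "n_unrecoverable"), 1L)
  expect_true(is.na(as.numeric(recover_se(0, 0.05))))

  # inverse consistency: p computed from (beta, se) recovers se
  set.seed(4)
  beta <- rnorm(200, 0, 0.2); se <- runif(200, 0.01, 0.2)
  p <- 2 * pnorm(abs(beta / se), lower.tail = FALSE)
  back <- as.numeric(recover_se(beta, p))
  expect_equal(back, se, tolerance = 1e-6)
})

test_that("harmonizing an already reference-oriented table is the identity", {
  panel <- depalindrome(make_panel(n = 100L, m = 60L, seed = 2L))
  tab <- make_scan(panel)
  h <- harmonize_study(tab, panel)
  expect_equal(h$report$counts$EXACT, 60L)
  expect_equal(h$report$n_retained, 60L)
  cols <- setdiff(names(tab$records), "in_reference")
  expect_equal(h$table$records[cols],
               tab$records[order(tab$records$chrom, tab$records$pos), cols],
               tolerance = 1e-12)
})

test_that("harmonization undoes a full allele swap (involution)", {
  panel <- make_panel(n = 100L, m = 80L, seed = 3L)
  tab <- make_scan(panel)
  h1 <- harmonize_study(tab, panel)$table
  h2 <- harmonize_study(swap_table(h1), panel)$table
  expect_equal(h2$records, h1$records, tolerance = 1e-12)
  # association strength |z| and p are preserved through the swap
  r1 <- h1$records[match(h2$records$snp_id, h1$records$snp_id), ]
  expect_equal(abs(h2$records$z), abs(r1$z))
  expect_equal(h2$records$p, r1$p)
})

test_that("swapped records come back sign-flipped with complemented eaf", {
  panel <- depalindrome(make_panel(n = 100L, m = 50L, seed = 8L))
  tab <- make_scan(panel)
  h0 <- harmonize_study(tab, panel)$table
  h1 <- harmonize_study(swap_table(h0), panel)
  expect_equal(h1$report$counts$SWAP, 50L)
  expect_equal(h1$table$records$beta, h0$records$beta)
  expect_equal(h1$table$records$eaf, h0$records$eaf)
})

test_that("strand-flipped records are recognized and statistics preserved", {
  panel <- depalindrome(make_panel(n = 100L, m = 50L, seed = 12L))
  tab <- make_scan(panel)
  r <- tab$records
  r$ea <- complement_alleles(r$ea)  # A/G becomes T/C: pure strand error
  r$oa <- complement_alleles(r$oa)
  flipped <- sumstats_table(r, tab$metadata)
  h <- harmonize_study(flipped, panel)
  expect_equal(h$report$counts$STRAND, 50L)
  h0 <- harmonize_study(tab, panel)$table
  expect_equal(h$table$records$beta, h0$records$beta)
  expect_equal(h$table$records$z, h0$records$z)
  expect_equal(h$table$records$ea, h0$records$ea)
})

test_that("high-MAF palindromic SNPs are dropped, counted, and absent", {
  panel <- depalindrome(make_panel(n = 200L, m = 40L, seed = 15L))
  # make one SNP palindromic with MAF ~ 0.45
  af <- panel$snp_map$alt_frequency
  j <- which.min(abs(af - 0.45))
  panel$snp_map$ref_allele[j] <- "A"
  panel$snp_map$alt_allele[j] <- "T"
  tab <- make_scan(panel)
  h <- harmonize_study(tab, panel)
  expect_equal(h$report$counts$AMBIGUOUS_DROPPED, 1L)
  expect_false(panel$snp_map$snp_id[j] %in% h$table$records$snp_id)
})

test_that("missing fields are reconstructed during harmonization", {
  panel <- depalindrome(make_panel(n = 150L, m = 40L, seed = 18L))
  tab <- make_scan(panel)
  r <- tab$records
  se_true <- r$se; eaf_true <- r$eaf; z_true <- r$z
  r$se <- NA_real_   # recoverable from beta + p
  r$eaf <- NA_real_  # fillable from the reference
  r$z <- NA_real_
  h <- harmonize_study(sumstats_table(r, tab$metadata), panel)
  rec <- h$table$records[match(tab$records$snp_id, h$table$records$snp_id), ]
  expect_equal(h$report$n_af_filled, 40L)
  expect_equal(h$report$n_se_recovered, 40L)
  expect_equal(rec$eaf, eaf_true)  # scan eaf equals panel frequency exactly
  # p came from the t distribution, so the normal-quantile recovery is close
  # but not exact at n = 150
  expect_equal(rec$se, se_true, tolerance = 2e-2)
  expect_equal(rec$z, rec$beta / rec$se)
})

test_that("records absent from the reference are retained and flagged", {
  panel <- depalindrome(make_panel(n = 100L, m = 30L, seed = 22L))
  tab <- make_scan(panel)
  r <- tab$records
  r$snp_id[1] <- "rs_unknown"      # id not in panel
  r$pos[2] <- r$pos[2] + 7L        # id match, discordant position
  h <- harmonize_study(sumstats_table(r, tab$metadata), panel)
  expect_equal(h$report$counts$NOT_IN_REFERENCE, 2L)
  rec <- h$table$records
  expect_false(rec$in_reference[rec$snp_id == "rs_unknown"])
  expect_equal(sum(!rec$in_reference), 2L)
  expect_equal(nrow(rec), 30L)
})
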