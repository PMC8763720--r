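# Locus-level colocalization: the SMR test, the HEIDI heterogeneity test,
# and the theta association-profile similarity metric.

#' Paired regional association profiles
#'
#' Bundles two traits' z-score vectors over one locus with the signed LD
#' (correlation) matrix of the locus and the index of the instrument SNP.
#' All z-scores must already share one allele orientation (harmonize both
#' studies to the same panel first).
#'
#' @param snp_ids Character vector of SNP ids.
#' @param z1,z2 Z-score vectors for the two traits (trait 2 is the
#'   exposure/instrument trait).
#' @param ld Signed correlation matrix (unit diagonal, entries in \[-1, 1\]).
#' @param top_index Index of the instrument SNP; defaults to the SNP with the
#'   largest |z2|.
#' @return A `region_profiles` object.
#' @export
region_profiles <- function(snp_ids, z1, z2, ld,
                            top_index = which.max(abs(z2))) {
  m <- length(snp_ids)
  stopifnot(length(z1) == m, length(z2) == m,
            is.matrix(ld), nrow(ld) == m, ncol(ld) == m,
            max(abs(diag(ld) - 1)) < 1e-8,
            top_index >= 1L, top_index <= m)
  structure(list(snp_ids = snp_ids, z1 = z1, z2 = z2, ld = ld,
                 top_index = as.integer(top_index)),
            class = "region_profiles")
}

#' Extract paired regional profiles from two harmonized studies
#'
#' Selects SNPs in `chrom:start-end` present in both studies and the panel
#' with finite z in both, and computes the signed LD matrix from the panel
#' haplotypes.
#'
#' @param t1,t2 Harmonized `sumstats_table`s (t2 = exposure trait).
#' @param panel The common `reference_panel`.
#' @param chrom,start,end Region coordinates (1-based, inclusive).
#' @return A `region_profiles` object.
#' @export
extract_region <- function(t1, t2, panel, chrom, start, end) {
  sm <- panel$snp_map
  in_reg <- sm$chrom == as.character(chrom) & sm$pos >= start & sm$pos <= end
  ids <- sm$snp_id[in_reg]
  z1all <- table_zscores(t1); z2all <- table_zscores(t2)
  i1 <- match(ids, t1$records$snp_id); i2 <- match(ids, t2$records$snp_id)
  ok <- !is.na(i1) & !is.na(i2) & is.finite(z1all[i1]) & is.finite(z2all[i2])
  if (sum(ok) < 2L) stop_input("fewer than 2 usable SNPs in region")
  ids <- ids[ok]
  cols <- match(ids, sm$snp_id)
  H <- panel$haplotypes[, cols, drop = FALSE]
  sdv <- apply(H, 2L, sd)
  if (any(sdv == 0)) stop_input("monomorphic SNP in region LD matrix")
  ld <- cor(H)
  region_profiles(ids, z1all[i1[ok]], z2all[i2[ok]], ld)
}

#' SMR colocalization test
#'
#' Tests whether two traits share an association at one SNP by combining the
#' two z-scores: t = z1^2 z2^2 / (z1^2 + z2^2), referred to the 1-df
#' chi-square upper tail.
#'
#' @param z1,z2 Z-scores of the same SNP for the two traits.
#' @return List with `t_smr` and `p_smr` (`NA` when both z are zero).
#' @export
smr_test <- function(z1, z2) {
  stopifnot(is.finite(z1), is.finite(z2))
  if (z1 == 0 && z2 == 0) return(list(t_smr = NA_real_, p_smr = NA_real_))
  t_smr <- z1^2 * z2^2 / (z1^2 + z2^2)
  list(t_smr = t_smr, p_smr = pchisq(t_smr, df = 1, lower.tail = FALSE))
}

#' Select SNPs for the HEIDI test
#'
#' Keeps SNPs whose exposure (trait-2) p-value is below `p_instrument_max`
#' and whose r^2 with the instrument SNP lies in \[`r2_min`, `r2_max`\];
#' greedily prunes mutually correlated pairs (r^2 > `r2_max`) keeping the
#' smaller exposure p, caps the set at `max_snps` by ascending p, and always
#' includes the instrument SNP.
#'
#' @param region A `region_profiles` object.
#' @param p_instrument_max Exposure significance cutoff (default 1.6e-4,
#'   |z| about 3.78).
#' @param r2_min,r2_max LD bounds with the instrument SNP.
#' @param max_snps Cap on the selected set.
#' @return Sorted integer indices into the region, instrument included.
#' @export
select_heidi_snps <- function(region, p_instrument_max = 1.6e-4,
                              r2_min = 0.05, r2_max = 0.9, max_snps = 20L) {
  stopifnot(inherits(region, "region_profiles"))
  top <- region$top_index
  p2 <- two_sided_p(region$z2)
  r2_top <- region$ld[, top]^2
  cand <- which(seq_along(p2) != top & p2 < p_instrument_max &
                  r2_top >= r2_min & r2_top <= r2_max)
  cand <- cand[order(p2[cand])]
  kept <- integer(0)
  for (j in cand) {
    if (all(region$ld[j, kept]^2 <= r2_max)) kept <- c(kept, j)
    if (length(kept) >= max_snps - 1L) break
  }
  sort(c(top, kept))
}

#' HEIDI heterogeneity test
#'
#' Tests whether the ratio of the two traits' standardized effects is
#' constant across the selected SNPs (the single-shared-causal-variant null)
#' against heterogeneity caused by distinct causal variants in LD. Per SNP,
#' b_i = z1_i / z2_i; deviations d_i = b_i - b_top are standardized using a
#' delta-method covariance derived from the LD matrix, and
#' T = sum (d_i / sd(d_i))^2 is referred to its null distribution — a weighted
#' sum of 1-df chi-squares with weights from the eigenvalues of the
#' correlation matrix of the standardized deviations — via seeded Monte Carlo.
#'
#' @param region A `region_profiles` object.
#' @param selected Indices from [select_heidi_snps()] (instrument included).
#' @param mc_draws Monte Carlo draws for the tail probability.
#' @param seed Seed for the Monte Carlo draws.
#' @return List with `p_heidi` (`NA` when fewer than 3 SNPs are selected),
#'   `n_heidi_snps` and `t_heidi`.
#' @export
heidi_test <- function(region, selected, mc_draws = 1e5, seed = 1L) {
  stopifnot(inherits(region, "region_profiles"))
  k <- length(selected)
  if (k < 3L)
    return(list(p_heidi = NA_real_, n_heidi_snps = k, t_heidi = NA_real_))
  top <- region$top_index
  stopifnot(top %in% selected)
  others <- setdiff(selected, top)
  z1 <- region$z1; z2 <- region$z2; R <- region$ld

  # Delta-method covariance of b_i = z1_i / z2_i around the observed values,
  # with cov(z1_i, z1_j) = cov(z2_i, z2_j) = r_ij and the traits independent.
  sel <- c(top, others)
  Cb <- outer(seq_along(sel), seq_along(sel), function(a, b) {
    i <- sel[a]; j <- sel[b]
    R[cbind(i, j)] / (z2[i] * z2[j]) +
      z1[i] * z1[j] * R[cbind(i, j)] / (z2[i]^2 * z2[j]^2)
  })
  # d_i = b_i - b_top for i != top: contrast against the first entry.
  A <- cbind(-1, diag(length(others)))
  V <- A %*% Cb %*% t(A)
  sdd <- sqrt(diag(V))
  b <- z1[sel] / z2[sel]
  d <- b[-1L] - b[1L]
  t_heidi <- sum((d / sdd)^2)

  Rd <- V / tcrossprod(sdd)
  if (inherits(try(chol(Rd), silent = TRUE), "try-error")) {
    warning("near-singular deviation covariance; ridge-regularizing diagonal")
    diag(V) <- diag(V) + 1e-8
    sdd <- sqrt(diag(V))
    Rd <- V / tcrossprod(sdd)
  }
  lam <- eigen(Rd, symmetric = TRUE, only.values = TRUE)$values
  lam <- pmax(lam, 0)
  p <- with_seed(seed, {
    draws <- matrix(rchisq(length(lam) * mc_draws, df = 1), nrow = length(lam))
    stat <- drop(lam %*% draws)
    (sum(stat >= t_heidi) + 1) / (mc_draws + 1)
  })
  list(p_heidi = p, n_heidi_snps = k, t_heidi = t_heidi)
}

#' Theta association-profile similarity
#'
#' Cosine similarity of the two orientation-harmonized z-score profiles over
#' a region: theta = sum(z1 z2) / sqrt(sum(z1^2) sum(z2^2)), in \[-1, 1\].
#' Identical profiles give 1, sign-reversed profiles -1, orthogonal
#' profiles 0.
#'
#' @param region A `region_profiles` object (or anything with `z1`, `z2`).
#' @return Theta, or `NA` when either profile is all zero.
#' @export
theta_metric <- function(region) {
  z1 <- region$z1; z2 <- region$z2
  stopifnot(length(z1) == length(z2), length(z1) >= 2L)
  n1 <- sum(z1^2); n2 <- sum(z2^2)
  if (n1 == 0 || n2 == 0) return(NA_real_)
  sum(z1 * z2) / sqrt(n1 * n2)
}

#' Full colocalization work-up of one locus
#'
#' Runs the SMR test at the instrument SNP, selects the HEIDI SNP set, runs
#' the HEIDI test, and computes theta over the region.
#'
#' @inheritParams heidi_test
#' @param p_instrument_max,r2_min,r2_max,max_snps Passed to
#'   [select_heidi_snps()].
#' @return One-row data frame: top_snp, t_smr, p_smr, p_heidi, n_heidi_snps,
#'   theta.
#' @export
coloc_locus <- function(region, p_instrument_max = 1.6e-4, r2_min = 0.05,
                        r2_max = 0.9, max_snps = 20L, mc_draws = 1e5,
                        seed = 1L) {
  top <- region$top_index
  smr <- smr_test(region$z1[top], region$z2[top])
  sel <- select_heidi_snps(region, p_instrument_max, r2_min, r2_max, max_snps)
  heidi <- heidi_test(region, sel, mc_draws = mc_draws, seed = seed)
  data.frame(top_snp = region$snp_ids[top], t_smr = smr$t_smr,
             p_smr = smr$p_smr, p_heidi = heidi$p_heidi,
             n_heidi_snps = heidi$n_heidi_snps,
             theta = theta_metric(region), stringsAsFactors = FALSE)
}
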