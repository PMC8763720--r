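# Study-level quality control: per-SNP concordance checks against the
# reference, distributional diagnostics, and the upload verdict.

# Median of the 1-df chi-square distribution, the null expectation that the
# genomic control factor divides by.
CHISQ1_MEDIAN <- qchisq(0.5, df = 1)

#' QC thresholds
#'
#' @param af_delta Maximum tolerated |eaf - ref_af| (default 0.2).
#' @param logp_delta Maximum tolerated |log10 p_reported - log10 p_computed|
#'   in decades (default 1.0).
#' @param skewness_max Maximum |skewness| of the effect-size distribution
#'   still considered symmetric (default 0.5).
#' @param outlier_fraction_max Outlying-SNP fraction above which a study is
#'   not recommended for upload (default 0.05; the verdict uses a strict
#'   "greater than").
#' @return A `qc_thresholds` list.
#' @export
qc_thresholds <- function(af_delta = 0.2, logp_delta = 1.0,
                          skewness_max = 0.5, outlier_fraction_max = 0.05) {
  stopifnot(af_delta > 0, logp_delta > 0, skewness_max > 0,
            outlier_fraction_max > 0, outlier_fraction_max < 1)
  structure(list(af_delta = af_delta, logp_delta = logp_delta,
                 skewness_max = skewness_max,
                 outlier_fraction_max = outlier_fraction_max),
            class = "qc_thresholds")
}

#' Allele-frequency concordance against the reference
#'
#' Flags a SNP when its study effect-allele frequency departs from the
#' reference alternate-allele frequency by more than `af_delta`. Assumes the
#' table is harmonized (reference-oriented). SNPs with missing eaf or absent
#' from the reference are unchecked and never flagged.
#'
#' @param table Harmonized `sumstats_table`.
#' @param panel A `reference_panel`.
#' @param af_delta Flagging threshold.
#' @return Data frame with `snp_id`, `checked`, `flag` and `delta`.
#' @export
af_concordance <- function(table, panel, af_delta = 0.2) {
  rec <- table$records
  idx <- match(rec$snp_id, panel$snp_map$snp_id)
  ref_af <- panel$snp_map$alt_frequency[idx]
  delta <- abs(rec$eaf - ref_af)
  checked <- !is.na(delta)
  flag <- checked & delta > af_delta
  data.frame(snp_id = rec$snp_id, checked = checked, flag = flag,
             delta = delta, stringsAsFactors = FALSE)
}

#' P-value / Z-statistic concordance
#'
#' Recomputes the two-sided normal p-value from |beta/se| and flags SNPs whose
#' reported p differs from it by more than `logp_delta` decades. Records
#' lacking beta, se or p are unchecked. The comparison is done on the log10
#' scale, so genome-wide-significant p-values do not underflow.
#'
#' @param table A `sumstats_table`.
#' @param logp_delta Flagging threshold in log10 units.
#' @return Data frame with `snp_id`, `checked`, `flag` and `log10_ratio`.
#' @export
pz_concordance <- function(table, logp_delta = 1.0) {
  rec <- table$records
  checked <- !is.na(rec$beta) & !is.na(rec$se) & !is.na(rec$p)
  lr <- rep(NA_real_, nrow(rec))
  zz <- rec$beta[checked] / rec$se[checked]
  lr[checked] <- log10(rec$p[checked]) - log10_two_sided_p(zz)
  flag <- checked & abs(lr) > logp_delta
  flag[is.na(flag)] <- FALSE
  data.frame(snp_id = rec$snp_id, checked = checked, flag = flag,
             log10_ratio = lr, stringsAsFactors = FALSE)
}

# Sample skewness g1 = m3 / m2^(3/2) with biased central moments.
sample_skewness <- function(x) {
  x <- x[!is.na(x)]
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 == 0) return(0)
  mean((x - m)^3) / m2^1.5
}

#' Symmetry diagnostics of the effect-size distribution
#'
#' Computes the sample skewness of beta and declares the distribution
#' symmetric when |skewness| does not exceed `skewness_max`. Fewer than 10
#' non-missing effects is an insufficient-data condition.
#'
#' @param table A `sumstats_table`.
#' @param skewness_max Symmetry bound.
#' @return List with `skewness`, `symmetric`, `n_beta` and `status`
#'   (`"ok"` or `"insufficient_data"`).
#' @export
effect_distribution_stats <- function(table, skewness_max = 0.5) {
  b <- table$records$beta
  b <- b[!is.na(b)]
  if (length(b) < 10L)
    return(list(skewness = NA_real_, symmetric = NA, n_beta = length(b),
                status = "insufficient_data"))
  g1 <- sample_skewness(b)
  list(skewness = g1, symmetric = abs(g1) <= skewness_max,
       n_beta = length(b), status = "ok")
}

table_zscores <- function(table) {
  rec <- table$records
  z <- rec$z
  use_bse <- is.na(z) & !is.na(rec$beta) & !is.na(rec$se)
  z[use_bse] <- rec$beta[use_bse] / rec$se[use_bse]
  z
}

#' Genomic control factor
#'
#' lambda_GC = median(z^2) / median of the 1-df chi-square (0.4549364).
#' Z-scores are taken from the z column or computed as beta/se.
#'
#' @param table A `sumstats_table`.
#' @return lambda_GC, or `NA` (with a warning) when fewer than 10 z-scores
#'   are available.
#' @export
genomic_control_lambda <- function(table) {
  z <- table_zscores(table)
  z <- z[!is.na(z)]
  if (length(z) < 10L) {
    warning("fewer than 10 usable z-scores; lambda_GC not computed")
    return(NA_real_)
  }
  median(z^2) / CHISQ1_MEDIAN
}

#' Trait variance implied by the summary statistics
#'
#' For a standardized additive model the per-SNP quantity
#' v_j = se_j^2 * n_j * 2 * eaf_j * (1 - eaf_j) approximates the phenotypic
#' variance; the median over eligible SNPs is returned as a robust estimate.
#'
#' @param table A `sumstats_table`.
#' @return Median implied variance, or `NA` when no SNP has se, n and eaf.
#' @export
estimate_trait_variance <- function(table) {
  rec <- table$records
  v <- rec$se^2 * rec$n * 2 * rec$eaf * (1 - rec$eaf)
  v <- v[!is.na(v)]
  if (length(v) == 0L) return(NA_real_)
  median(v)
}

#' Study-level QC verdict
#'
#' Runs the full battery — allele-frequency concordance, p/Z concordance,
#' effect-size symmetry, implied trait variance and lambda_GC — and issues the
#' upload verdict: `"not_recommended"` when the outlying-SNP fraction strictly
#' exceeds `outlier_fraction_max` or the effect-size distribution is
#' asymmetric, else `"recommended"`. A SNP is an outlier when any per-SNP flag
#' is set; SNPs unchecked by both per-SNP tests are excluded from the
#' denominator. The verdict is advisory: [register_study()] accepts a
#' not-recommended study with `force = TRUE`.
#'
#' @param table Harmonized `sumstats_table`.
#' @param panel A `reference_panel`.
#' @param thresholds A [qc_thresholds()] object.
#' @return A `qc_report`: per-SNP flags, `lambda_gc`, `trait_variance`,
#'   `effect_skewness`, `outlier_fraction`, `n_checked`, `verdict`. The
#'   report is also attached to the returned table's twin via
#'   [attach_qc()] convenience in callers.
#' @export
qc_verdict <- function(table, panel, thresholds = qc_thresholds()) {
  stopifnot(inherits(thresholds, "qc_thresholds"))
  af <- af_concordance(table, panel, thresholds$af_delta)
  pz <- pz_concordance(table, thresholds$logp_delta)
  checked <- af$checked | pz$checked
  outlier <- af$flag | pz$flag
  n_checked <- sum(checked)
  outlier_fraction <- if (n_checked > 0L) sum(outlier) / n_checked else NA_real_

  eff <- effect_distribution_stats(table, thresholds$skewness_max)
  lambda <- suppressWarnings(genomic_control_lambda(table))
  tv <- estimate_trait_variance(table)

  asymmetric <- identical(eff$symmetric, FALSE)
  too_many <- !is.na(outlier_fraction) &&
    outlier_fraction > thresholds$outlier_fraction_max
  verdict <- if (too_many || asymmetric) "not_recommended" else "recommended"

  structure(list(
    snp_flags = data.frame(snp_id = af$snp_id, af_outlier = af$flag,
                           pz_outlier = pz$flag, checked = checked,
                           stringsAsFactors = FALSE),
    lambda_gc = lambda, trait_variance = tv,
    effect_skewness = eff$skewness,
    outlier_fraction = outlier_fraction, n_checked = n_checked,
    thresholds = thresholds, verdict = verdict),
    class = "qc_report")
}

#' Attach a QC report to a table
#'
#' @param table A `sumstats_table`.
#' @param report A `qc_report` from [qc_verdict()].
#' @return The table with the report stored in its `"qc_report"` attribute.
#' @export
attach_qc <- function(table, report) {
  stopifnot(inherits(report, "qc_report"))
  attr(table, "qc_report") <- report
  table
}

#' @export
print.qc_report <- function(x, ...) {
  cat("<qc_report>\n")
  cat(sprintf("  lambda_GC        %.4f\n", x$lambda_gc))
  cat(sprintf("  trait variance   %s\n",
              if (is.na(x$trait_variance)) "NA" else sprintf("%.4f", x$trait_variance)))
  cat(sprintf("  effect skewness  %s\n",
              if (is.na(x$effect_skewness)) "NA" else sprintf("%.4f", x$effect_skewness)))
  cat(sprintf("  outliers         %.2f%% of %d checked\n",
              100 * x$outlier_fraction, x$n_checked))
  cat(sprintf("  verdict          %s\n", x$verdict))
  invisible(x)
}
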