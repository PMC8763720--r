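# LD-score computation from a haplotype panel and LD-score regression for
# SNP heritability and cross-trait genetic correlation.

#' Compute LD scores from a reference panel
#'
#' For SNP j, l_j = 1 + sum of adjusted squared correlations with SNPs within
#' `window` positions on the same chromosome, where
#' r~^2 = r^2 - (1 - r^2)/(n - 2) is the finite-sample-unbiased adjustment
#' and r the haplotype Pearson correlation (n = haplotype count). Monomorphic
#' SNPs get l = 1 and are flagged.
#'
#' @param panel A `reference_panel` with at least 50 haplotypes.
#' @param window Window half-width in SNP count (default 100).
#' @param window_bp Optional window half-width in base pairs, applied in
#'   addition to `window` (for panels with a physical map).
#' @return An `ld_scores` data frame: chrom, snp_id, pos, l2, monomorphic;
#'   attributes `window`, `window_bp`, `n_ref`.
#' @export
compute_ld_scores <- function(panel, window = 100L, window_bp = NULL) {
  stopifnot(inherits(panel, "reference_panel"))
  H <- panel$haplotypes
  n <- nrow(H)
  if (n <= 2L) stop_input("need more than 2 haplotypes to compute LD scores")
  if (n < 50L) warning("fewer than 50 haplotypes; LD scores will be noisy")
  m <- ncol(H)
  sm <- panel$snp_map
  sdv <- apply(H, 2L, sd)
  poly <- sdv > 0
  Hs <- sweep(H, 2L, colMeans(H), "-")
  Hs[, poly] <- sweep(Hs[, poly, drop = FALSE], 2L, sdv[poly], "/")
  Hs[, !poly] <- 0

  l2 <- rep(1, m)
  window <- as.integer(window)
  chunk <- 512L
  for (start in seq(1L, m, by = chunk)) {
    jr <- start:min(start + chunk - 1L, m)
    nr <- max(1L, jr[1L] - window):min(m, jr[length(jr)] + window)
    r <- crossprod(Hs[, jr, drop = FALSE], Hs[, nr, drop = FALSE]) / (n - 1)
    r2 <- r^2
    r2adj <- r2 - (1 - r2) / (n - 2)
    for (a in seq_along(jr)) {
      j <- jr[a]
      if (!poly[j]) next
      k <- nr[nr != j & abs(nr - j) <= window & sm$chrom[nr] == sm$chrom[j] &
                poly[nr]]
      if (!is.null(window_bp))
        k <- k[abs(sm$pos[k] - sm$pos[j]) <= window_bp]
      if (length(k))
        l2[j] <- 1 + sum(r2adj[a, match(k, nr)])
    }
  }
  structure(data.frame(chrom = sm$chrom, snp_id = sm$snp_id, pos = sm$pos,
                       l2 = l2, monomorphic = !poly, stringsAsFactors = FALSE),
            window = window, window_bp = window_bp, n_ref = n,
            class = c("ld_scores", "data.frame"))
}

#' Write LD scores in the conventional l2 layout
#'
#' Columns CHR, SNP, POS, L2, tab-separated.
#'
#' @param scores An `ld_scores` data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ld_scores <- function(scores, path) {
  out <- data.frame(CHR = scores$chrom, SNP = scores$snp_id,
                    POS = scores$pos, L2 = scores$l2)
  data.table::fwrite(out, path, sep = "\t", quote = FALSE)
  invisible(path)
}

# Weighted least squares; returns c(intercept, slope) or just the slope when
# the intercept is constrained.
wls_fit <- function(x, y, w, intercept = TRUE, offset = 0) {
  y <- y - offset
  if (intercept) {
    X <- cbind(1, x)
    b <- solve(crossprod(X, w * X), crossprod(X, w * y))
    c(intercept = b[1L] + offset, slope = b[2L])
  } else {
    c(intercept = offset, slope = sum(w * x * y) / sum(w * x^2))
  }
}

ldsc_join <- function(table, scores) {
  z <- table_zscores(table)
  idx <- match(scores$snp_id, table$records$snp_id)
  ok <- !is.na(idx) & !is.na(z[idx]) & !scores$monomorphic
  list(l = scores$l2[ok], z = z[idx[ok]], n_snps = sum(ok))
}

jackknife_blocks <- function(m, n_blocks) {
  split(seq_len(m), cut(seq_len(m), breaks = n_blocks, labels = FALSE))
}

jackknife_se <- function(est) {
  est <- est[!is.na(est)]
  B <- length(est)
  sqrt((B - 1) / B * sum((est - mean(est))^2))
}

# Two-step heteroskedasticity weighting shared by the h2 and cross-trait
# regressions. Step 1 uses 1/max(l, 1); step 2 divides by the squared fitted
# expectation of the response, floored to keep weights finite.
ldsc_step2_weights <- function(l, w0, mu1, mu2 = mu1, cross = NULL) {
  f1 <- pmax(mu1, 0.1); f2 <- pmax(mu2, 0.1)
  denom <- if (is.null(cross)) 2 * f1^2 else f1 * f2 + cross^2
  w0 / denom
}

#' SNP heritability by LD-score regression
#'
#' Regresses per-SNP chi-square (z^2) on N * l_j / M; the slope estimates h2
#' and the intercept absorbs confounding inflation. Two-step
#' heteroskedasticity weighting: initial weights 1/max(l, 1), refit with the
#' squared fitted mean chi-square in the denominator. Standard errors by
#' leave-one-block-out jackknife over contiguous position-sorted blocks.
#'
#' @param table Harmonized `sumstats_table` with z or beta/se.
#' @param scores `ld_scores` from [compute_ld_scores()] on the same panel.
#' @param m Number of SNPs the heritability refers to (default: all
#'   polymorphic score SNPs).
#' @param n GWAS sample size (default: median of the table's n column).
#' @param n_blocks Jackknife block count (default 20).
#' @param intercept_one Constrain the intercept to 1 (useful in small
#'   simulations free of confounding).
#' @return An `h2_estimate`: h2, h2_se, intercept, intercept_se, m_snps,
#'   n_blocks.
#' @export
estimate_h2 <- function(table, scores, m = NULL, n = NULL, n_blocks = 20L,
                        intercept_one = FALSE) {
  stopifnot(inherits(scores, "ld_scores"), n_blocks >= 2L)
  j <- ldsc_join(table, scores)
  if (is.null(m)) m <- sum(!scores$monomorphic)
  if (is.null(n)) n <- median(table$records$n, na.rm = TRUE)
  if (is.na(n)) stop_input("sample size n unavailable; supply n explicitly")
  if (j$n_snps < 10L * n_blocks)
    stop_input("only ", j$n_snps, " usable SNPs for ", n_blocks,
               " jackknife blocks; reduce n_blocks")
  l <- j$l; chi2 <- j$z^2
  x <- n * l / m
  w0 <- 1 / pmax(l, 1)
  fit0 <- wls_fit(x, chi2, w0, intercept = !intercept_one, offset = 1)
  mu <- x * max(fit0[["slope"]], 0) + fit0[["intercept"]]
  w <- ldsc_step2_weights(l, w0, mu)
  fit <- wls_fit(x, chi2, w, intercept = !intercept_one, offset = 1)

  blocks <- jackknife_blocks(length(x), n_blocks)
  jk <- vapply(blocks, function(b)
    wls_fit(x[-b], chi2[-b], w[-b], intercept = !intercept_one, offset = 1),
    numeric(2))
  structure(list(h2 = fit[["slope"]], h2_se = jackknife_se(jk["slope", ]),
                 intercept = fit[["intercept"]],
                 intercept_se = if (intercept_one) 0 else
                   jackknife_se(jk["intercept", ]),
                 m_snps = j$n_snps, n_blocks = n_blocks,
                 n = n, m = m),
            class = "h2_estimate")
}

#' @export
print.h2_estimate <- function(x, ...) {
  cat(sprintf("<h2_estimate> h2 = %.4f (SE %.4f), intercept = %.4f (SE %.4f), %d SNPs\n",
              x$h2, x$h2_se, x$intercept, x$intercept_se, x$m_snps))
  invisible(x)
}

#' Genetic correlation by cross-trait LD-score regression
#'
#' Regresses z1_j * z2_j on sqrt(n1 n2) * l_j / M; the slope estimates the
#' genetic covariance rho_g and the intercept absorbs sample overlap. Each
#' trait's h2 is estimated on the shared SNPs with the same machinery, and
#' rg = rho_g / sqrt(h2_1 * h2_2). The jackknife recomputes all three slopes
#' per left-out block, so the reported SE applies to rg itself.
#'
#' @param t1,t2 Harmonized `sumstats_table`s sharing the reference
#'   orientation.
#' @param scores `ld_scores` on the common panel.
#' @param m,n_blocks As in [estimate_h2()].
#' @param n1,n2 Sample sizes of the two studies (defaults: their n medians).
#' @return An `rg_estimate`: rho_g, rg, rg_se, cross_intercept, h2_1, h2_2,
#'   out_of_range flag (|rg| > 1 from sampling noise).
#' @export
genetic_correlation <- function(t1, t2, scores, m = NULL, n1 = NULL, n2 = NULL,
                                n_blocks = 20L) {
  stopifnot(inherits(scores, "ld_scores"))
  z1all <- table_zscores(t1); z2all <- table_zscores(t2)
  i1 <- match(scores$snp_id, t1$records$snp_id)
  i2 <- match(scores$snp_id, t2$records$snp_id)
  ok <- !is.na(i1) & !is.na(i2) & !is.na(z1all[i1]) & !is.na(z2all[i2]) &
    !scores$monomorphic
  if (!any(ok)) stop_input("no overlapping SNPs between the two studies")
  l <- scores$l2[ok]; z1 <- z1all[i1[ok]]; z2 <- z2all[i2[ok]]
  if (is.null(m)) m <- sum(!scores$monomorphic)
  if (is.null(n1)) n1 <- median(t1$records$n, na.rm = TRUE)
  if (is.null(n2)) n2 <- median(t2$records$n, na.rm = TRUE)
  if (length(l) < 10L * n_blocks)
    stop_input("only ", length(l), " shared SNPs for ", n_blocks,
               " jackknife blocks; reduce n_blocks")

  w0 <- 1 / pmax(l, 1)
  x1 <- n1 * l / m; x2 <- n2 * l / m; x12 <- sqrt(n1 * n2) * l / m
  # Step 1 on all three regressions.
  f1_0 <- wls_fit(x1, z1^2, w0, offset = 1)
  f2_0 <- wls_fit(x2, z2^2, w0, offset = 1)
  fc_0 <- wls_fit(x12, z1 * z2, w0, offset = 0)
  # Step 2 weights from fitted means; the cross denominator f1*f2 + c^2
  # reduces to the h2 denominator 2*f^2 when the two traits coincide.
  mu1 <- x1 * max(f1_0[["slope"]], 0) + f1_0[["intercept"]]
  mu2 <- x2 * max(f2_0[["slope"]], 0) + f2_0[["intercept"]]
  muc <- x12 * fc_0[["slope"]] + fc_0[["intercept"]]
  w1 <- ldsc_step2_weights(l, w0, mu1)
  w2 <- ldsc_step2_weights(l, w0, mu2)
  wc <- ldsc_step2_weights(l, w0, mu1, mu2, cross = muc)
  fit1 <- wls_fit(x1, z1^2, w1, offset = 1)
  fit2 <- wls_fit(x2, z2^2, w2, offset = 1)
  fitc <- wls_fit(x12, z1 * z2, wc, offset = 0)

  h2_1 <- fit1[["slope"]]; h2_2 <- fit2[["slope"]]
  rho_g <- fitc[["slope"]]
  rg <- if (h2_1 > 0 && h2_2 > 0) rho_g / sqrt(h2_1 * h2_2) else NA_real_

  blocks <- jackknife_blocks(length(l), n_blocks)
  rg_b <- vapply(blocks, function(b) {
    s1 <- wls_fit(x1[-b], z1[-b]^2, w1[-b], offset = 1)[["slope"]]
    s2 <- wls_fit(x2[-b], z2[-b]^2, w2[-b], offset = 1)[["slope"]]
    sc <- wls_fit(x12[-b], (z1 * z2)[-b], wc[-b], offset = 0)[["slope"]]
    if (s1 > 0 && s2 > 0) sc / sqrt(s1 * s2) else NA_real_
  }, numeric(1))
  structure(list(rho_g = rho_g, rg = rg, rg_se = jackknife_se(rg_b),
                 cross_intercept = fitc[["intercept"]],
                 h2_1 = h2_1, h2_2 = h2_2, n_snps = length(l),
                 n_blocks = n_blocks,
                 out_of_range = !is.na(rg) && abs(rg) > 1),
            class = "rg_estimate")
}

#' @export
print.rg_estimate <- function(x, ...) {
  cat(sprintf("<rg_estimate> rg = %.4f (SE %.4f), rho_g = %.4f, cross intercept = %.4f\n",
              x$rg, x$rg_se, x$rho_g, x$cross_intercept))
  if (x$out_of_range) cat("  note: |rg| > 1 (sampling noise)\n")
  invisible(x)
}
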