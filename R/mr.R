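# Two-sample Mendelian randomization: instrument selection by significance
# and LD clumping, then IVW, Egger and weighted-median estimators.

#' Select and clump MR instruments
#'
#' Takes exposure SNPs with p below `p_max`, greedily clumps them (iterating
#' by ascending p, discarding any SNP with r^2 above `clump_r2` to an already
#' retained SNP within `clump_window` base pairs, r^2 from the panel
#' haplotypes), and joins the survivors to the outcome study by snp_id.
#'
#' @param exposure,outcome Harmonized `sumstats_table`s sharing the panel
#'   orientation.
#' @param panel The common `reference_panel`.
#' @param p_max Exposure significance threshold (default 5e-8).
#' @param clump_r2 LD pruning threshold (default 0.01).
#' @param clump_window Clumping window in base pairs (default 500 kb).
#' @return Data frame of instruments: snp_id, beta_x, se_x, beta_y, se_y,
#'   p_x; class `mr_instruments`.
#' @export
select_instruments <- function(exposure, outcome, panel, p_max = 5e-8,
                               clump_r2 = 0.01, clump_window = 5e5) {
  ex <- exposure$records
  sm <- panel$snp_map
  idx <- match(ex$snp_id, sm$snp_id)
  sig <- which(!is.na(ex$p) & ex$p < p_max & !is.na(idx) &
                 !is.na(ex$beta) & !is.na(ex$se))
  sig <- sig[order(ex$p[sig])]
  if (length(sig) == 0L)
    stop_input("no instrument passes p < ", p_max,
               "; consider relaxing p_max")
  H <- panel$haplotypes
  kept <- integer(0)
  for (j in sig) {
    ok <- TRUE
    for (k in kept) {
      same_chr <- sm$chrom[idx[j]] == sm$chrom[idx[k]]
      near <- same_chr &&
        abs(sm$pos[idx[j]] - sm$pos[idx[k]]) <= clump_window
      if (near && cor(H[, idx[j]], H[, idx[k]])^2 > clump_r2) {
        ok <- FALSE; break
      }
    }
    if (ok) kept <- c(kept, j)
  }
  out <- outcome$records
  oidx <- match(ex$snp_id[kept], out$snp_id)
  ok <- !is.na(oidx) & !is.na(out$beta[oidx]) & !is.na(out$se[oidx])
  kept <- kept[ok]; oidx <- oidx[ok]
  if (length(kept) == 0L)
    stop_input("no clumped instrument present in the outcome study")
  structure(data.frame(snp_id = ex$snp_id[kept],
                       beta_x = ex$beta[kept], se_x = ex$se[kept],
                       beta_y = out$beta[oidx], se_y = out$se[oidx],
                       p_x = ex$p[kept], stringsAsFactors = FALSE),
            class = c("mr_instruments", "data.frame"))
}

mr_result <- function(method, estimate, se, n_instruments,
                      egger_intercept = NA_real_,
                      egger_intercept_se = NA_real_) {
  structure(list(method = method, estimate = estimate, se = se,
                 p = two_sided_p(estimate / se),
                 egger_intercept = egger_intercept,
                 egger_intercept_se = egger_intercept_se,
                 n_instruments = n_instruments),
            class = "mr_result")
}

#' @export
print.mr_result <- function(x, ...) {
  cat(sprintf("<mr_result:%s> estimate = %.4f (SE %.4f, p = %.3g), %d instruments\n",
              x$method, x$estimate, x$se, x$p, x$n_instruments))
  if (!is.na(x$egger_intercept))
    cat(sprintf("  egger intercept = %.4f (SE %.4f)\n",
                x$egger_intercept, x$egger_intercept_se))
  invisible(x)
}

ratio_estimates <- function(instruments, second_order = FALSE) {
  ins <- as.data.frame(instruments)
  zero <- ins$beta_x == 0
  if (any(zero)) {
    warning(sum(zero), " instrument(s) with beta_x = 0 dropped")
    ins <- ins[!zero, , drop = FALSE]
  }
  # Delta-method SE of the ratio: first order ignores the se_x term; the
  # second-order form adds the exposure-noise contribution.
  se <- if (second_order)
    sqrt(ins$se_y^2 / ins$beta_x^2 +
           ins$beta_y^2 * ins$se_x^2 / ins$beta_x^4)
  else ins$se_y / abs(ins$beta_x)
  list(w = ins$beta_y / ins$beta_x, se = se, ins = ins)
}

#' Inverse-variance-weighted MR
#'
#' Combines per-instrument ratio estimates beta_y/beta_x with first-order
#' delta-method SEs se_y/|beta_x| by inverse-variance weighting.
#'
#' @param instruments Data frame from [select_instruments()] (or with the
#'   same columns).
#' @param second_order Use the second-order delta SE (adds the exposure-noise
#'   term se_x; first order is the standard baseline).
#' @return An `mr_result`.
#' @export
mr_ivw <- function(instruments, second_order = FALSE) {
  r <- ratio_estimates(instruments, second_order)
  if (length(r$w) < 2L) stop_input("IVW needs at least 2 instruments")
  wt <- 1 / r$se^2
  est <- sum(wt * r$w) / sum(wt)
  mr_result("ivw", est, 1 / sqrt(sum(wt)), length(r$w))
}

#' MR-Egger regression
#'
#' Weighted least squares of beta_y on beta_x with a free intercept (weights
#' 1/se_y^2) after re-orienting instruments so all beta_x >= 0. The slope is
#' the causal estimate; the intercept gauges directional pleiotropy.
#'
#' @param instruments As in [mr_ivw()]; at least 3 required.
#' @return An `mr_result` with `egger_intercept` populated.
#' @export
mr_egger <- function(instruments) {
  ins <- as.data.frame(instruments)
  if (nrow(ins) < 3L) stop_input("Egger regression needs at least 3 instruments")
  flip <- ins$beta_x < 0
  ins$beta_x[flip] <- -ins$beta_x[flip]
  ins$beta_y[flip] <- -ins$beta_y[flip]
  if (var(ins$beta_x) == 0)
    stop_input("degenerate design: all |beta_x| identical")
  fit <- stats::lm(beta_y ~ beta_x, data = ins, weights = 1 / ins$se_y^2)
  cf <- summary(fit)$coefficients
  mr_result("egger", cf["beta_x", 1L], cf["beta_x", 2L], nrow(ins),
            egger_intercept = cf["(Intercept)", 1L],
            egger_intercept_se = cf["(Intercept)", 2L])
}

weighted_median_est <- function(w, wt) {
  o <- order(w)
  w <- w[o]; wt <- wt[o] / sum(wt)
  cs <- cumsum(wt) - wt / 2
  if (all(cs < 0.5)) return(w[length(w)])
  if (cs[1L] >= 0.5) return(w[1L])
  below <- max(which(cs < 0.5))
  w[below] + (w[below + 1L] - w[below]) * (0.5 - cs[below]) /
    (cs[below + 1L] - cs[below])
}

#' Weighted-median MR
#'
#' Weighted median of the ratio estimates with inverse-variance weights;
#' consistent when at least half the weight comes from valid instruments.
#' SE by seeded parametric bootstrap of (beta_x, beta_y) from their reported
#' normals.
#'
#' @param instruments As in [mr_ivw()]; at least 3 required.
#' @param n_boot Bootstrap draws (default 1000).
#' @param seed Bootstrap seed.
#' @return An `mr_result`.
#' @export
mr_weighted_median <- function(instruments, n_boot = 1000L, seed = 1L) {
  r <- ratio_estimates(instruments)
  if (length(r$w) < 3L)
    stop_input("weighted median needs at least 3 instruments")
  est <- weighted_median_est(r$w, 1 / r$se^2)
  ins <- r$ins
  boot <- with_seed(seed, vapply(seq_len(n_boot), function(i) {
    bx <- rnorm(nrow(ins), ins$beta_x, ins$se_x)
    by <- rnorm(nrow(ins), ins$beta_y, ins$se_y)
    ok <- bx != 0
    wb <- by[ok] / bx[ok]
    sb <- ins$se_y[ok] / abs(bx[ok])
    weighted_median_est(wb, 1 / sb^2)
  }, numeric(1)))
  mr_result("weighted_median", est, sd(boot), length(r$w))
}

#' Run a panel of MR estimators
#'
#' @param instruments As in [mr_ivw()].
#' @param methods Subset of `c("ivw", "egger", "weighted_median")`.
#' @param seed Seed for the weighted-median bootstrap.
#' @return Data frame with one row per method: method, estimate, se, p,
#'   egger_intercept, n_instruments.
#' @export
mr_analysis <- function(instruments,
                        methods = c("ivw", "egger", "weighted_median"),
                        seed = 1L) {
  methods <- match.arg(methods, several.ok = TRUE)
  rows <- lapply(methods, function(m) {
    r <- switch(m, ivw = mr_ivw(instruments), egger = mr_egger(instruments),
                weighted_median = mr_weighted_median(instruments, seed = seed))
    data.frame(method = r$method, estimate = r$estimate, se = r$se, p = r$p,
               egger_intercept = r$egger_intercept,
               n_instruments = r$n_instruments, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
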