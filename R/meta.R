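# Fixed-effect meta-analysis of harmonized studies: inverse-variance
# weighting of effect sizes and sample-size-weighted (Stouffer) z-scores.

stack_tables <- function(tables) {
  stopifnot(length(tables) >= 1L,
            all(vapply(tables, inherits, logical(1), "sumstats_table")))
  do.call(rbind, lapply(seq_along(tables), function(i) {
    r <- tables[[i]]$records[CANONICAL_FIELDS]
    r$.study <- i
    r
  }))
}

#' Check compatibility of studies intended for meta-analysis
#'
#' Reports per-study lambda_GC and implied trait variance, pairwise SNP
#' overlap, and allele-orientation agreement on shared SNPs (which must be
#' 100 % after harmonization to a common reference).
#'
#' @param tables List of at least two harmonized `sumstats_table`s.
#' @return A `meta_check` list with `per_study` (data frame: study_id,
#'   n_records, lambda_gc, trait_variance), `pairwise` (data frame: study
#'   pair, n_overlap, n_orientation_conflicts) and `ok` (no pair with zero
#'   overlap or orientation conflicts).
#' @export
check_meta_inputs <- function(tables) {
  stopifnot(length(tables) >= 2L)
  per_study <- do.call(rbind, lapply(tables, function(t)
    data.frame(study_id = t$metadata$study_id, n_records = nrow(t$records),
               lambda_gc = suppressWarnings(genomic_control_lambda(t)),
               trait_variance = estimate_trait_variance(t),
               stringsAsFactors = FALSE)))
  pairs <- utils::combn(length(tables), 2L)
  pairwise <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(k) {
    i <- pairs[1L, k]; j <- pairs[2L, k]
    ri <- tables[[i]]$records; rj <- tables[[j]]$records
    shared <- intersect(ri$snp_id, rj$snp_id)
    mi <- match(shared, ri$snp_id); mj <- match(shared, rj$snp_id)
    conflicts <- sum(ri$ea[mi] != rj$ea[mj] | ri$oa[mi] != rj$oa[mj])
    data.frame(study_1 = tables[[i]]$metadata$study_id,
               study_2 = tables[[j]]$metadata$study_id,
               n_overlap = length(shared),
               n_orientation_conflicts = conflicts,
               stringsAsFactors = FALSE)
  }))
  if (any(pairwise$n_overlap == 0L))
    stop_input("zero SNP overlap between studies ",
               paste(pairwise$study_1[pairwise$n_overlap == 0L],
                     pairwise$study_2[pairwise$n_overlap == 0L],
                     sep = " / ", collapse = "; "))
  structure(list(per_study = per_study, pairwise = pairwise,
                 ok = all(pairwise$n_orientation_conflicts == 0L)),
            class = "meta_check")
}

#' Inverse-variance-weighted meta-analysis
#'
#' Per SNP, with weights w_i = 1/se_i^2: beta = sum(w b)/sum(w),
#' se = sum(w)^(-1/2), z = beta/se, plus Cochran's Q and I^2 heterogeneity.
#' SNPs present in only a subset of studies are combined over that subset
#' (`k_studies` records how many) unless `complete_cases = TRUE`. The output
#' effect-allele frequency is the sample-size-weighted mean of study eafs.
#'
#' @param tables List of harmonized `sumstats_table`s (same reference
#'   orientation; see [check_meta_inputs()]).
#' @param min_studies Drop SNPs contributed by fewer studies than this.
#' @param complete_cases Keep only SNPs present in every study.
#' @return Data frame of meta records: snp_id, chrom, pos, ea, oa, eaf,
#'   beta_meta, se_meta, z_meta, p_meta, n_total, k_studies, het_q, het_i2.
#' @export
meta_ivw <- function(tables, min_studies = 1L, complete_cases = FALSE) {
  long <- stack_tables(tables)
  long <- long[!is.na(long$beta) & !is.na(long$se), , drop = FALSE]
  dt <- data.table::as.data.table(long)
  k_all <- length(tables)
  res <- dt[, {
    w <- 1 / se^2
    bm <- sum(w * beta) / sum(w)
    sem <- 1 / sqrt(sum(w))
    q <- sum(w * (beta - bm)^2)
    k <- .N
    i2 <- if (q > 0) max(0, 1 - (k - 1) / q) else 0
    nw <- if (all(is.na(n))) rep(1, .N) else ifelse(is.na(n), 0, n)
    eafm <- if (all(is.na(eaf))) NA_real_ else
      sum(nw * eaf, na.rm = TRUE) / sum(nw[!is.na(eaf)])
    list(chrom = chrom[1L], pos = pos[1L], ea = ea[1L], oa = oa[1L],
         eaf = eafm, beta_meta = bm, se_meta = sem, z_meta = bm / sem,
         n_total = if (all(is.na(n))) NA_integer_ else sum(n, na.rm = TRUE),
         k_studies = k, het_q = q, het_i2 = i2)
  }, by = snp_id]
  res <- as.data.frame(res)
  res$p_meta <- two_sided_p(res$z_meta)
  if (complete_cases) min_studies <- max(min_studies, k_all)
  res <- res[res$k_studies >= min_studies, , drop = FALSE]
  res <- res[order(res$chrom, res$pos), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Sample-size-weighted z-score meta-analysis
#'
#' Stouffer combination with sqrt(n) weights:
#' z = sum(sqrt(n_i) z_i) / sqrt(sum n_i). Yields direction and significance
#' only; beta and se are left missing. Records lacking n are skipped and
#' counted in the `"n_skipped_missing_n"` attribute.
#'
#' @inheritParams meta_ivw
#' @return Data frame of meta records with z_meta, p_meta, n_total,
#'   k_studies (beta_meta and se_meta `NA`).
#' @export
meta_zscore <- function(tables, min_studies = 1L, complete_cases = FALSE) {
  long <- stack_tables(tables)
  z <- long$z
  use_bse <- is.na(z) & !is.na(long$beta) & !is.na(long$se)
  z[use_bse] <- long$beta[use_bse] / long$se[use_bse]
  long$z <- z
  usable <- !is.na(long$z) & !is.na(long$n)
  n_skipped <- length(unique(long$snp_id[!usable]))
  long <- long[usable, , drop = FALSE]
  dt <- data.table::as.data.table(long)
  res <- dt[, {
    zm <- sum(sqrt(n) * z) / sqrt(sum(n))
    list(chrom = chrom[1L], pos = pos[1L], ea = ea[1L], oa = oa[1L],
         eaf = if (all(is.na(eaf))) NA_real_ else
           sum(n[!is.na(eaf)] * eaf[!is.na(eaf)]) / sum(n[!is.na(eaf)]),
         beta_meta = NA_real_, se_meta = NA_real_, z_meta = zm,
         n_total = sum(n), k_studies = .N,
         het_q = NA_real_, het_i2 = NA_real_)
  }, by = snp_id]
  res <- as.data.frame(res)
  res$p_meta <- two_sided_p(res$z_meta)
  if (complete_cases) min_studies <- max(min_studies, length(tables))
  res <- res[res$k_studies >= min_studies, , drop = FALSE]
  res <- res[order(res$chrom, res$pos), , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "n_skipped_missing_n") <- n_skipped
  res
}
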