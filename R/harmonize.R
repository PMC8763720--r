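# Allele alignment of study records to a reference panel: resolves swaps,
# strand flips and palindromic ambiguity, and reconstructs derivable fields.

ALIGNMENT_CODES <- c("EXACT", "SWAP", "STRAND", "STRAND_SWAP",
                     "AMBIGUOUS_RESOLVED", "AMBIGUOUS_DROPPED",
                     "MISMATCH", "NOT_IN_REFERENCE")

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

#' Complement nucleotide alleles
#' @param x Character vector over A/C/G/T.
#' @return The complementary bases.
#' @export
complement_alleles <- function(x) unname(COMPLEMENT[x])

is_palindromic <- function(ea, oa) oa == unname(COMPLEMENT[ea])

#' Align one study allele pair to the reference orientation
#'
#' The canonical orientation takes the reference panel's alternate allele as
#' the effect allele. The study pair may match exactly, be swapped, lie on the
#' opposite strand, or both. Palindromic pairs (A/T, C/G) cannot be oriented
#' by strand; they are resolved by comparing allele frequencies, but only when
#' both study and reference minor-allele frequencies are below
#' `ambiguity_threshold` — otherwise the record is dropped as ambiguous.
#'
#' Vectorized over all arguments.
#'
#' @param ea,oa Study effect and other alleles (A/C/G/T).
#' @param ref_allele,alt_allele Reference panel alleles.
#' @param study_eaf Study effect-allele frequency (may be `NA`).
#' @param ref_af Reference alternate-allele frequency.
#' @param ambiguity_threshold MAF bound below which palindromic pairs are
#'   frequency-resolved (default 0.4).
#' @return Data frame with `code` (alignment outcome), `sign_flip` and
#'   `eaf_complemented` logicals. Sign flips apply to beta and z;
#'   `eaf_complemented` means the study frequency refers to the reference
#'   ref allele and must be replaced by 1 - eaf.
#' @export
align_alleles <- function(ea, oa, ref_allele, alt_allele,
                          study_eaf = NA_real_, ref_af,
                          ambiguity_threshold = 0.4) {
  nn <- max(length(ea), length(oa), length(ref_allele), length(alt_allele),
            length(ref_af))
  ea <- rep_len(ea, nn); oa <- rep_len(oa, nn)
  ref_allele <- rep_len(ref_allele, nn); alt_allele <- rep_len(alt_allele, nn)
  study_eaf <- rep_len(study_eaf, nn); ref_af <- rep_len(ref_af, nn)

  code <- rep("MISMATCH", nn)
  flip <- rep(FALSE, nn)

  pal <- is_palindromic(ea, oa)
  same_pair <- (ea == alt_allele & oa == ref_allele) |
               (ea == ref_allele & oa == alt_allele)

  # Palindromic study pair over the same base set as the reference pair:
  # strand is unknowable, so orientation comes from frequency alone.
  amb <- pal & same_pair
  if (any(amb)) {
    maf_study <- pmin(study_eaf, 1 - study_eaf)
    maf_ref <- pmin(ref_af, 1 - ref_af)
    resolvable <- amb & !is.na(study_eaf) &
      maf_study < ambiguity_threshold & maf_ref < ambiguity_threshold
    code[amb] <- "AMBIGUOUS_DROPPED"
    # Orientation minimizing the frequency discrepancy: as-is (effect allele
    # already the alt allele) versus swapped (effect allele is the ref allele).
    swapped_better <- abs((1 - study_eaf) - ref_af) < abs(study_eaf - ref_af)
    code[resolvable] <- "AMBIGUOUS_RESOLVED"
    flip[resolvable] <- swapped_better[resolvable]
  }

  plain <- !amb
  exact <- plain & ea == alt_allele & oa == ref_allele
  swap <- plain & ea == ref_allele & oa == alt_allele
  cea <- unname(COMPLEMENT[ea]); coa <- unname(COMPLEMENT[oa])
  strand <- plain & !exact & !swap & cea == alt_allele & coa == ref_allele
  strand_swap <- plain & !exact & !swap & cea == ref_allele & coa == alt_allele
  code[exact] <- "EXACT"
  code[swap] <- "SWAP"; flip[swap] <- TRUE
  code[strand] <- "STRAND"
  code[strand_swap] <- "STRAND_SWAP"; flip[strand_swap] <- TRUE

  data.frame(code = code, sign_flip = flip, eaf_complemented = flip,
             stringsAsFactors = FALSE)
}

#' Z-score from a two-sided p-value and a sign source
#'
#' |z| is the upper-tail standard-normal quantile at p/2; the sign is copied
#' from `sign_source` (typically the effect size). `z_from_p(1, x)` is 0.
#' P-values below the smallest positive normal double are clamped, with a
#' warning, to avoid quantile overflow.
#'
#' @param p P-values in (0, 1].
#' @param sign_source Values whose signs are transferred to z.
#' @return Z-scores.
#' @export
z_from_p <- function(p, sign_source) {
  if (any(!is.na(p) & (p <= 0 | p > 1)))
    stop_input("p-values must lie in (0, 1]")
  tiny <- .Machine$double.xmin
  clamped <- !is.na(p) & p < tiny
  if (any(clamped)) {
    warning("p-value(s) below double precision clamped to ", tiny)
    p[clamped] <- tiny
  }
  z <- qnorm(p / 2, lower.tail = FALSE)
  s <- sign(sign_source)
  s[s == 0] <- 1
  out <- z * s
  out[!is.na(p) & p == 1] <- 0
  out
}

#' Recover the standard error from effect size and p-value
#'
#' se = |beta| / |z(p)| with z the two-sided normal quantile. Unrecoverable
#' when beta = 0 or p = 1 (z = 0); those entries stay `NA`.
#'
#' @param beta Effect sizes.
#' @param p Two-sided p-values in (0, 1].
#' @return Standard errors (`NA` where unrecoverable); attribute
#'   `"n_unrecoverable"` counts failures among non-missing inputs.
#' @export
recover_se <- function(beta, p) {
  z <- abs(z_from_p(p, 1))
  ok <- !is.na(beta) & !is.na(z) & beta != 0 & z > 0
  se <- rep(NA_real_, length(beta))
  se[ok] <- abs(beta[ok]) / z[ok]
  structure(se, n_unrecoverable = sum(!ok & !is.na(beta) & !is.na(p)))
}

#' Harmonize a study to a reference panel
#'
#' Matches records to the panel by snp_id (with chromosome/position used as
#' verification: an id match at a discordant position is treated as not in the
#' reference), orients every matched record so the panel's alternate allele is
#' the effect allele (flipping beta/z signs and complementing eaf where
#' needed), drops allele mismatches and unresolvable palindromic records, and
#' fills derivable missing fields: eaf from the reference frequency, se from
#' beta and p, z from beta/se or from p and the beta sign, p from z. Records
#' absent from the reference are retained, flagged by the `in_reference`
#' column, and left untouched. Output is sorted by (chrom, pos).
#'
#' @param table A `sumstats_table`.
#' @param panel A `reference_panel`.
#' @param ambiguity_threshold Palindromic MAF bound, see [align_alleles()].
#' @return List with `table` (harmonized `sumstats_table`, extra logical
#'   column `in_reference`) and `report` (`harmonization_report`: counts per
#'   alignment outcome plus `n_se_recovered` and `n_af_filled`).
#' @export
harmonize_study <- function(table, panel, ambiguity_threshold = 0.4) {
  stopifnot(inherits(table, "sumstats_table"), inherits(panel, "reference_panel"))
  rec <- table$records
  sm <- panel$snp_map
  idx <- match(rec$snp_id, sm$snp_id)
  pos_ok <- !is.na(idx) & rec$chrom == sm$chrom[idx] & rec$pos == sm$pos[idx]
  idx[!pos_ok] <- NA_integer_

  code <- rep("NOT_IN_REFERENCE", nrow(rec))
  flip <- rep(FALSE, nrow(rec))
  m <- !is.na(idx)
  if (any(m)) {
    al <- align_alleles(rec$ea[m], rec$oa[m],
                        sm$ref_allele[idx[m]], sm$alt_allele[idx[m]],
                        rec$eaf[m], sm$alt_frequency[idx[m]],
                        ambiguity_threshold)
    code[m] <- al$code
    flip[m] <- al$sign_flip
  }
  counts <- table(factor(code, levels = ALIGNMENT_CODES))

  keep <- !(code %in% c("MISMATCH", "AMBIGUOUS_DROPPED"))
  rec <- rec[keep, , drop = FALSE]
  idx <- idx[keep]; flip <- flip[keep]
  m <- !is.na(idx)

  # Orient to the reference: alt allele becomes the effect allele.
  rec$beta[flip] <- -rec$beta[flip]
  rec$z[flip] <- -rec$z[flip]
  rec$eaf[flip] <- 1 - rec$eaf[flip]
  rec$ea[m] <- sm$alt_allele[idx[m]]
  rec$oa[m] <- sm$ref_allele[idx[m]]

  # Fill derivable fields.
  need_af <- m & is.na(rec$eaf)
  rec$eaf[need_af] <- sm$alt_frequency[idx[need_af]]
  n_af_filled <- sum(need_af)

  need_se <- is.na(rec$se) & !is.na(rec$beta) & !is.na(rec$p)
  if (any(need_se))
    rec$se[need_se] <- as.numeric(recover_se(rec$beta[need_se], rec$p[need_se]))
  n_se_recovered <- sum(need_se & !is.na(rec$se))

  need_z <- is.na(rec$z)
  from_bse <- need_z & !is.na(rec$beta) & !is.na(rec$se)
  rec$z[from_bse] <- rec$beta[from_bse] / rec$se[from_bse]
  from_p <- is.na(rec$z) & !is.na(rec$p) & !is.na(rec$beta)
  if (any(from_p))
    rec$z[from_p] <- z_from_p(rec$p[from_p], rec$beta[from_p])
  need_p <- is.na(rec$p) & !is.na(rec$z)
  rec$p[need_p] <- two_sided_p(rec$z[need_p])

  rec$in_reference <- m
  rec <- rec[order(rec$chrom, rec$pos), , drop = FALSE]
  out <- new_sumstats_table(rec, table$metadata)

  report <- structure(list(counts = as.list(counts),
                           n_input = length(code),
                           n_retained = nrow(rec),
                           n_se_recovered = n_se_recovered,
                           n_af_filled = n_af_filled),
                      class = "harmonization_report")
  list(table = out, report = report)
}

#' @export
print.harmonization_report <- function(x, ...) {
  cat("<harmonization_report>\n")
  for (cd in names(x$counts))
    if (x$counts[[cd]] > 0) cat(sprintf("  %-20s %d\n", cd, x$counts[[cd]]))
  cat(sprintf("  retained %d / %d; se recovered %d; eaf filled %d\n",
              x$n_retained, x$n_input, x$n_se_recovered, x$n_af_filled))
  invisible(x)
}
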