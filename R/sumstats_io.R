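# Canonical record model ------------------------------------------------------

# Internal column names of a sumstats table, in canonical order, and the
# headers used in the canonical TSV serialization.
CANONICAL_FIELDS <- c("snp_id", "chrom", "pos", "ea", "oa",
                      "eaf", "beta", "se", "p", "z", "n")
CANONICAL_HEADERS <- c("SNP", "CHR", "POS", "EA", "OA",
                       "EAF", "BETA", "SE", "P", "Z", "N")
VALID_ALLELES <- c("A", "C", "G", "T")
STUDY_DOMAINS <- c("complex_trait", "mQTL", "pQTL", "glycan", "eQTL")

#' Study metadata record
#'
#' Descriptive metadata attached to one summary-statistics table: identifier,
#' trait name, omics domain, sample size and provenance.
#'
#' @param study_id Unique study identifier string.
#' @param trait_name Human-readable trait name.
#' @param domain One of `"complex_trait"`, `"mQTL"`, `"pQTL"`, `"glycan"`,
#'   `"eQTL"`.
#' @param sample_size Integer sample size (> 0) or `NA`.
#' @param collection,ancestry,genome_build,source Free-text provenance fields.
#' @return A `study_metadata` list.
#' @export
study_metadata <- function(study_id, trait_name, domain = "complex_trait",
                           sample_size = NA_integer_, collection = "",
                           ancestry = "EUR", genome_build = "GRCh37",
                           source = "") {
  stopifnot(is.character(study_id), length(study_id) == 1L, nzchar(study_id))
  domain <- match.arg(domain, STUDY_DOMAINS)
  if (!is.na(sample_size)) {
    sample_size <- as.integer(sample_size)
    if (sample_size <= 0L) stop_input("sample_size must be positive")
  }
  structure(list(study_id = study_id, trait_name = trait_name, domain = domain,
                 collection = collection, sample_size = sample_size,
                 ancestry = ancestry, genome_build = genome_build,
                 source = source),
            class = "study_metadata")
}

#' Column dialect of a summary-statistics source file
#'
#' Describes how one source file maps onto the canonical record model: which
#' source header corresponds to which canonical field, the field delimiter,
#' which strings encode missing values, and whether the p-value column holds
#' -log10(p) rather than p.
#'
#' @param column_map Named character vector or list mapping source header
#'   names to canonical field names (`snp_id`, `chrom`, `pos`, `ea`, `oa`,
#'   `eaf`, `beta`, `se`, `p`, `z`, `n`). Must cover `snp_id` plus at least
#'   one association statistic.
#' @param delimiter Single field-delimiter character.
#' @param missing_codes Strings interpreted as missing values.
#' @param p_is_log10 If `TRUE` the p column holds -log10(p); values are
#'   converted to p = 10^(-value) on read.
#' @return A `dialect_spec` list.
#' @export
dialect_spec <- function(column_map, delimiter = "\t",
                         missing_codes = c("NA", ".", "", "NaN"),
                         p_is_log10 = FALSE) {
  column_map <- unlist(column_map)
  stopifnot(is.character(column_map), !is.null(names(column_map)))
  bad <- setdiff(unname(column_map), CANONICAL_FIELDS)
  if (length(bad))
    stop_input("unknown canonical field(s) in column_map: ",
               paste(bad, collapse = ", "))
  stats_present <- intersect(unname(column_map), c("beta", "se", "p", "z"))
  if (!"snp_id" %in% column_map || length(stats_present) == 0L)
    stop_input("column_map must cover snp_id and at least one association statistic")
  structure(list(column_map = column_map, delimiter = delimiter,
                 missing_codes = missing_codes,
                 p_is_log10 = isTRUE(p_is_log10)),
            class = "dialect_spec")
}

#' The canonical TSV dialect
#'
#' Dialect of the package's own output format (headers SNP, CHR, POS, EA, OA,
#' EAF, BETA, SE, P, Z, N).
#'
#' @return A `dialect_spec`.
#' @export
canonical_dialect <- function() {
  dialect_spec(setNames(CANONICAL_FIELDS, CANONICAL_HEADERS))
}

new_sumstats_table <- function(records, metadata) {
  stopifnot(inherits(metadata, "study_metadata"), is.data.frame(records))
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  missing_cols <- setdiff(CANONICAL_FIELDS, names(records))
  for (cc in missing_cols)
    records[[cc]] <- if (cc %in% c("pos", "n")) NA_integer_ else
      if (cc %in% c("snp_id", "chrom", "ea", "oa")) NA_character_ else NA_real_
  records <- records[, union(CANONICAL_FIELDS,
                             setdiff(names(records), CANONICAL_FIELDS))]
  if (anyDuplicated(records$snp_id))
    stop_input("duplicate snp_id values in summary statistics")
  rownames(records) <- NULL
  structure(list(metadata = metadata, records = records),
            class = "sumstats_table")
}

#' Build a summary-statistics table from a data frame
#'
#' @param records Data frame with (a subset of) the canonical fields
#'   `snp_id`, `chrom`, `pos`, `ea`, `oa`, `eaf`, `beta`, `se`, `p`, `z`, `n`.
#' @param metadata A [study_metadata()] record.
#' @return A `sumstats_table`.
#' @export
sumstats_table <- function(records, metadata) new_sumstats_table(records, metadata)

#' @export
print.sumstats_table <- function(x, ...) {
  cat(sprintf("<sumstats_table> %s (%s), %d records\n",
              x$metadata$study_id, x$metadata$domain, nrow(x$records)))
  print(head(x$records, 5L))
  invisible(x)
}

#' Number of records in a sumstats table
#' @param x A `sumstats_table`.
#' @export
n_records <- function(x) nrow(x$records)

# Reading ----------------------------------------------------------------------

#' Read a summary-statistics file under a column dialect
#'
#' Converts a delimited source file into the canonical record model. Missing
#' codes are mapped to `NA`, alleles are uppercased, -log10(p) columns are
#' converted to p-values, rows with unparseable chromosome/position or alleles
#' outside A/C/G/T are dropped and counted. Gzip input is read transparently.
#'
#' @param path Path to a delimited text file (optionally `.gz`).
#' @param dialect A [dialect_spec()].
#' @param metadata A [study_metadata()] record for the study.
#' @return A `sumstats_table`; the attribute `"parse_report"` holds counts of
#'   input rows and rows dropped by each rule.
#' @export
read_sumstats <- function(path, dialect, metadata) {
  stopifnot(inherits(dialect, "dialect_spec"))
  if (!file.exists(path)) stop_input("file not found: ", path)
  raw <- if (grepl("\\.gz$", path)) {
    con <- gzfile(path, "rt")
    on.exit(close(con), add = TRUE)
    data.table::fread(text = readLines(con), sep = dialect$delimiter,
                      header = TRUE, colClasses = "character",
                      data.table = FALSE, na.strings = NULL,
                      showProgress = FALSE)
  } else {
    data.table::fread(path, sep = dialect$delimiter, header = TRUE,
                      colClasses = "character", data.table = FALSE,
                      na.strings = NULL, showProgress = FALSE)
  }
  if (nrow(raw) == 0L) stop_input("empty summary-statistics file: ", path)
  cmap <- dialect$column_map
  absent <- setdiff(names(cmap), names(raw))
  if (length(absent))
    stop_input("dialect maps column(s) absent from file: ",
               paste(absent, collapse = ", "))

  out <- data.frame(row.names = seq_len(nrow(raw)))
  for (src in names(cmap)) out[[cmap[[src]]]] <- raw[[src]]
  for (cc in setdiff(CANONICAL_FIELDS, names(out))) out[[cc]] <- NA_character_
  out <- out[CANONICAL_FIELDS]

  miss <- function(x) replace(x, x %in% dialect$missing_codes, NA_character_)
  out[] <- lapply(out, miss)

  n_input <- nrow(out)
  suppressWarnings({
    out$pos <- as.integer(out$pos)
    for (cc in c("eaf", "beta", "se", "p", "z")) out[[cc]] <- as.numeric(out[[cc]])
    out$n <- as.integer(round(as.numeric(out$n)))
  })
  out$ea <- toupper(out$ea); out$oa <- toupper(out$oa)

  bad_pos <- is.na(out$snp_id) | is.na(out$chrom) | is.na(out$pos) | out$pos < 1L
  out <- out[!bad_pos, , drop = FALSE]
  bad_allele <- !(out$ea %in% VALID_ALLELES) | !(out$oa %in% VALID_ALLELES) |
    out$ea == out$oa
  out <- out[!bad_allele, , drop = FALSE]

  if (dialect$p_is_log10) out$p <- 10^(-out$p)
  out$p[!is.na(out$p) & (out$p <= 0 | out$p > 1)] <- NA_real_
  out$eaf[!is.na(out$eaf) & (out$eaf < 0 | out$eaf > 1)] <- NA_real_
  out$se[!is.na(out$se) & out$se <= 0] <- NA_real_

  tab <- new_sumstats_table(out, metadata)
  attr(tab, "parse_report") <- list(
    n_input = n_input,
    n_dropped_position = sum(bad_pos),
    n_dropped_allele = sum(bad_allele),
    n_retained = nrow(out))
  tab
}

# Writing ----------------------------------------------------------------------

#' Write a summary-statistics table in the canonical TSV format
#'
#' Columns SNP, CHR, POS, EA, OA, EAF, BETA, SE, P, Z, N in fixed order;
#' missing values as `NA`; reals serialized at full precision so that
#' read-after-write reproduces the table. A `.gz` suffix gzips the output.
#'
#' @param table A `sumstats_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sumstats <- function(table, path) {
  stopifnot(inherits(table, "sumstats_table"))
  rec <- table$records[CANONICAL_FIELDS]
  names(rec) <- CANONICAL_HEADERS
  data.table::fwrite(rec, path, sep = "\t", na = "NA", quote = FALSE,
                     compress = if (grepl("\\.gz$", path)) "gzip" else "none")
  invisible(path)
}

# Reference panel --------------------------------------------------------------

new_reference_panel <- function(snp_map, haplotypes, n_skipped = 0L) {
  stopifnot(is.data.frame(snp_map), is.matrix(haplotypes),
            nrow(snp_map) == ncol(haplotypes))
  o <- order(snp_map$chrom, snp_map$pos)
  snp_map <- snp_map[o, , drop = FALSE]
  haplotypes <- haplotypes[, o, drop = FALSE]
  rownames(snp_map) <- NULL
  snp_map$alt_frequency <- colMeans(haplotypes)
  colnames(haplotypes) <- snp_map$snp_id
  structure(list(snp_map = snp_map, haplotypes = haplotypes,
                 n_skipped = n_skipped),
            class = "reference_panel")
}

#' Build a reference panel from a SNP map and haplotype matrix
#'
#' @param snp_map Data frame with columns snp_id, chrom, pos, ref_allele,
#'   alt_allele (alt_frequency is recomputed from the haplotypes).
#' @param haplotypes 0/1 matrix, one row per haplotype (2 per individual),
#'   one column per SNP, column order matching `snp_map`.
#' @return A `reference_panel`, columns sorted by (chrom, pos).
#' @export
reference_panel <- function(snp_map, haplotypes) {
  stopifnot(all(c("snp_id", "chrom", "pos", "ref_allele", "alt_allele")
                %in% names(snp_map)),
            all(haplotypes %in% c(0L, 1L)))
  if (anyDuplicated(snp_map$snp_id)) stop_input("duplicate snp_id in snp_map")
  new_reference_panel(
    snp_map[, c("snp_id", "chrom", "pos", "ref_allele", "alt_allele")],
    haplotypes)
}

#' @export
print.reference_panel <- function(x, ...) {
  cat(sprintf("<reference_panel> %d SNPs, %d haplotypes (%d individuals)\n",
              nrow(x$snp_map), nrow(x$haplotypes), nrow(x$haplotypes) %/% 2L))
  invisible(x)
}

#' Load a phased reference panel from a VCF file
#'
#' Keeps biallelic SNP records (single-base REF and ALT in A/C/G/T); indels
#' and multiallelic records are skipped and counted. Genotypes must be phased
#' (`|` separator); the haplotype matrix has one row per haplotype (2 per
#' individual) and one 0/1 column per SNP. Alternate-allele frequencies are
#' recomputed from the haplotypes.
#'
#' @param vcf_path Path to a VCF file (optionally bgzipped).
#' @return A `reference_panel` with `snp_map` (snp_id, chrom, pos, ref_allele,
#'   alt_allele, alt_frequency) and `haplotypes`; `n_skipped` counts excluded
#'   records.
#' @export
load_reference <- function(vcf_path) {
  v <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  if (nrow(fix) == 0L) stop_input("no records in VCF: ", vcf_path)
  keep <- fix$REF %in% VALID_ALLELES & fix$ALT %in% VALID_ALLELES
  n_skipped <- sum(!keep)
  if (!any(keep)) stop_input("no usable biallelic SNP records in VCF: ", vcf_path)
  gt <- vcfR::extract.gt(v, element = "GT")
  gt <- gt[keep, , drop = FALSE]
  fix <- fix[keep, , drop = FALSE]
  unphased <- grepl("/", gt, fixed = TRUE)
  if (any(unphased)) {
    i <- (which(unphased)[1L] - 1L) %% nrow(gt) + 1L
    stop_input("unphased genotypes in VCF at record ", fix$ID[i],
               " (", fix$CHROM[i], ":", fix$POS[i], ")")
  }
  a1 <- substr(gt, 1L, 1L)
  a2 <- substr(gt, 3L, 3L)
  if (!all(c(a1, a2) %in% c("0", "1")))
    stop_input("non-biallelic or missing GT codes in VCF")
  m <- nrow(gt); n_ind <- ncol(gt)
  hap <- matrix(0L, nrow = 2L * n_ind, ncol = m)
  hap[seq(1L, 2L * n_ind, by = 2L), ] <- t(matrix(as.integer(a1), m, n_ind))
  hap[seq(2L, 2L * n_ind, by = 2L), ] <- t(matrix(as.integer(a2), m, n_ind))
  ids <- fix$ID
  noid <- is.na(ids) | ids == "."
  ids[noid] <- paste(fix$CHROM[noid], fix$POS[noid], fix$REF[noid],
                     fix$ALT[noid], sep = ":")
  snp_map <- data.frame(snp_id = ids, chrom = fix$CHROM,
                        pos = as.integer(fix$POS),
                        ref_allele = fix$REF, alt_allele = fix$ALT,
                        stringsAsFactors = FALSE)
  if (anyDuplicated(snp_map$snp_id)) stop_input("duplicate SNP ids in VCF")
  new_reference_panel(snp_map, hap, n_skipped = n_skipped)
}

#' Write a reference panel as a phased VCF
#'
#' Minimal VCFv4.2 serialization of a `reference_panel`: one biallelic SNP
#' record per column with phased GT fields. Round-trips through
#' [load_reference()].
#'
#' @param panel A `reference_panel`.
#' @param path Output path (plain text).
#' @return `path`, invisibly.
#' @export
write_panel_vcf <- function(panel, path) {
  stopifnot(inherits(panel, "reference_panel"))
  H <- panel$haplotypes
  n_ind <- nrow(H) %/% 2L
  sm <- panel$snp_map
  samples <- sprintf("IND%04d", seq_len(n_ind))
  gt_a <- H[seq(1L, 2L * n_ind, by = 2L), , drop = FALSE]
  gt_b <- H[seq(2L, 2L * n_ind, by = 2L), , drop = FALSE]
  gt <- matrix(paste0(t(gt_a), "|", t(gt_b)), nrow = ncol(H))
  body <- paste(sm$chrom, sm$pos, sm$snp_id, sm$ref_allele, sm$alt_allele,
                ".", "PASS", ".", "GT",
                apply(gt, 1L, paste, collapse = "\t"), sep = "\t")
  header <- c("##fileformat=VCFv4.2",
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", samples), collapse = "\t"))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Subset a reference panel to a set of individuals
#'
#' @param panel A `reference_panel`.
#' @param individuals Integer indices of individuals (1-based) to keep.
#' @return A `reference_panel` restricted to those individuals, with
#'   alternate-allele frequencies recomputed.
#' @export
subset_panel <- function(panel, individuals) {
  rows <- as.vector(rbind(2L * individuals - 1L, 2L * individuals))
  new_reference_panel(panel$snp_map[, c("snp_id", "chrom", "pos",
                                        "ref_allele", "alt_allele")],
                      panel$haplotypes[rows, , drop = FALSE],
                      n_skipped = panel$n_skipped)
}

#' Diploid allele-dosage matrix of a panel
#'
#' @param panel A `reference_panel`.
#' @return Integer matrix, individuals x SNPs, entries 0/1/2 counting
#'   alternate alleles.
#' @export
panel_genotypes <- function(panel) {
  H <- panel$haplotypes
  n_ind <- nrow(H) %/% 2L
  H[seq(1L, nrow(H), by = 2L), , drop = FALSE] +
    H[seq(2L, nrow(H), by = 2L), , drop = FALSE]
}
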