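# Fixtures built in code: small panels, studies and files shared across the
# test files. Everything is seeded and regenerated at test time.

test_meta <- function(id = "study1", domain = "complex_trait", n = 500L) {
  study_metadata(id, trait_name = paste(id, "trait"), domain = domain,
                 sample_size = n)
}

# A small LD-structured panel plus a matching clean scan.
make_panel <- function(n = 200L, m = 120L, seed = 7L, ld_rho = 0.5,
                       maf_range = c(0.05, 0.5)) {
  simulate_panel(sim_config(n_individuals = n, m_snps = m, ld_rho = ld_rho,
                            maf_range = maf_range, seed = seed))
}

# Replace a panel's allele labels with a fixed non-palindromic pair so every
# alignment outcome is EXACT/SWAP/STRAND rather than frequency-resolved.
depalindrome <- function(panel) {
  panel$snp_map$ref_allele <- "A"
  panel$snp_map$alt_allele <- "G"
  colnames(panel$haplotypes) <- panel$snp_map$snp_id
  panel
}

make_scan <- function(panel, cfg_seed = 11L, h2 = 0.5,
                      n_causal = max(1L, ncol(panel$haplotypes) %/% 10L)) {
  n <- nrow(panel$haplotypes) %/% 2L
  cfg <- sim_config(n_individuals = n, m_snps = ncol(panel$haplotypes),
                    h2 = h2, n_causal = n_causal, seed = cfg_seed)
  ph <- simulate_phenotype(panel, cfg)
  gwas_scan(panel, ph$phenotype, test_meta(n = n))
}

# Hand-built 3-record table used by the IO tests.
basic_records <- function() {
  data.frame(
    snp_id = c("rs1", "rs2", "rs3"), chrom = c("1", "1", "2"),
    pos = c(100L, 200L, 50L), ea = c("A", "C", "G"), oa = c("G", "T", "A"),
    eaf = c(0.25, 0.5, NA), beta = c(0.1, -0.2, 0.05),
    se = c(0.02, 0.05, 0.01), p = c(5.733031e-07, 6.334248e-05, 5.733031e-07),
    z = c(5, -4, 5), n = c(1000L, 1000L, 1000L),
    stringsAsFactors = FALSE)
}

# Swap the allele orientation of every record (the involution partner).
swap_table <- function(table) {
  r <- table$records
  tmp <- r$ea; r$ea <- r$oa; r$oa <- tmp
  r$beta <- -r$beta
  r$z <- -r$z
  r$eaf <- 1 - r$eaf
  sumstats_table(r, table$metadata)
}

# Tiny hand-written VCF used by load_reference tests: 4 individuals; 5
# biallelic SNPs plus 1 indel record that must be skipped.
write_fixture_vcf <- function(path, unphased_record = FALSE) {
  gts <- list(
    rs101 = c("0|0", "0|1", "1|1", "0|0"),
    rs102 = c("0|1", "0|1", "0|0", "1|1"),
    rs103 = c("1|1", "1|0", "0|0", "0|1"),
    indel1 = c("0|0", "0|1", "0|0", "0|0"),
    rs104 = c("0|0", "0|0", "0|1", "0|0"),
    rs105 = c("1|0", "0|0", "0|0", "0|0"))
  ref <- c("A", "C", "G", "AT", "T", "C")
  alt <- c("G", "T", "A", "A", "C", "G")
  pos <- c(100, 200, 300, 400, 500, 600)
  if (unphased_record) gts$rs103[2] <- "1/0"
  body <- vapply(seq_along(gts), function(i)
    paste(c("1", pos[i], names(gts)[i], ref[i], alt[i], ".", "PASS", ".",
            "GT", gts[[i]]), collapse = "\t"), character(1))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", paste0("S", 1:4)), collapse = "\t"),
               body), path)
  path
}
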