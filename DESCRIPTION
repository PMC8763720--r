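Package: gwaskit
Title: Harmonization, Quality Control and Analysis of GWAS Summary Statistics
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Unifies heterogeneous genome-wide association study (GWAS) summary
    statistics into a single canonical record model and provides the standard
    downstream toolchain. Reads arbitrary column dialects into one table format,
    aligns every record to a reference haplotype panel (allele swaps, strand
    flips, palindromic-SNP resolution), reconstructs missing fields (standard
    errors from effect sizes and p-values, allele frequencies from the
    reference), and runs a quality-control battery: allele-frequency
    concordance, p-value/Z-statistic consistency, effect-size symmetry, implied
    trait variance, and the genomic control factor (lambda GC). On harmonized
    tables it offers inverse-variance and sample-size weighted meta-analysis,
    LD-score regression for SNP heritability and genetic correlation, SMR and
    HEIDI colocalization tests with an association-profile similarity metric,
    and two-sample Mendelian randomization (IVW, Egger, weighted median) with
    LD clumping of instruments. A synthetic-data module simulates LD-structured
    haplotype panels, polygenic phenotypes with controlled heritability,
    per-SNP regression scans, and targeted data corruptions for validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    vcfR,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
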