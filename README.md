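# gwaskit

Tools for working with GWAS summary statistics end to end: harmonizing
heterogeneous per-SNP association files against a reference haplotype panel,
auditing them with a quality-control battery before they enter a shared
store, and analysing them with the standard summary-level methods —
meta-analysis, LD-score regression, SMR/HEIDI colocalization and two-sample
Mendelian randomization. It is aimed at groups that accumulate association
results from many sources (complex traits, mQTL, pQTL, glycan and eQTL
scans) and need one consistent record model plus a reproducible QC gate in
front of every downstream analysis.

## The record model

Every study is a `sumstats_table`: study metadata plus one row per SNP with
the canonical fields

```
SNP  CHR  POS  EA  OA  EAF  BETA  SE  P  Z  N
```

where `EA` is the effect allele, `BETA` the additive per-allele effect,
`EAF` the effect-allele frequency. Arbitrary source dialects are described
by a `dialect_spec` (column map, delimiter, missing codes, optional
-log10(p) column) and converted on read. A `reference_panel` (phased VCF or
simulated) supplies the SNP map, allele pairs, frequencies and LD.

## Methods at a glance

- **Harmonization** orients every record so the panel's alternate allele is
  the effect allele, resolving swaps (sign flip, `EAF -> 1 - EAF`) and
  strand flips (base complement). Palindromic pairs (A/T, C/G) are resolved
  by frequency only when both study and reference MAF < 0.4, else dropped.
  Missing fields are reconstructed: `SE = |beta| / z(p)` with
  `z(p) = Phi^{-1}(1 - p/2)`, z from `beta/se`, frequencies from the panel.
- **QC battery**: allele-frequency concordance (`|EAF - ref| > 0.2` flags a
  SNP), p/Z consistency (reported p vs `2(1 - Phi(|beta/se|))`, flagged
  beyond one decade), effect-size skewness `g1 = m3/m2^{3/2}` (symmetric iff
  `|g1| <= 0.5`), implied trait variance `median(se^2 n 2p(1-p))`, and the
  genomic control factor `lambda_GC = median(z^2)/0.4549`. A study is **not
  recommended** for upload when more than 5 % of checked SNPs are outliers
  or the effect distribution is asymmetric; the verdict is advisory and can
  be overridden at registration.
- **Meta-analysis**: fixed-effect inverse-variance weighting
  (`w = 1/se^2`, with Cochran's Q and I^2) and the sample-size-weighted
  z-score method `z = sum(sqrt(n_i) z_i)/sqrt(sum n_i)`.
- **LD-score regression**: per-SNP scores
  `l_j = 1 + sum r~^2` (adjusted `r~^2 = r^2 - (1-r^2)/(n-2)`) over a SNP
  window; `chi^2_j` regressed on `N l_j / M` with two-step
  heteroskedasticity weights gives SNP heritability (slope) and the
  confounding intercept; the cross-trait version estimates genetic
  covariance and `rg = rho_g / sqrt(h2_1 h2_2)`. Standard errors by
  leave-one-block-out jackknife.
- **Colocalization**: SMR statistic `t = z1^2 z2^2/(z1^2 + z2^2)` (1-df
  chi-square), the HEIDI heterogeneity test on z-ratios with a delta-method
  covariance from the LD matrix, and the theta profile-similarity metric
  (cosine of the two regional z-vectors).
- **Mendelian randomization**: instrument selection by `p < 5e-8` with
  greedy LD clumping (`r^2 < 0.01`), then IVW, MR-Egger and weighted-median
  estimators on the per-instrument ratios `beta_y/beta_x`.
- **Simulator**: LD-structured haplotypes (Markov copy model with
  recombination-hotspot LD blocks), additive polygenic phenotypes with
  controlled h2, per-SNP regression scans, and targeted corruptions
  (frequency flips, p scrambles, beta inflation, strand errors) for
  validation.

## Worked example

```r
library(gwaskit)

cfg   <- sim_config(n_individuals = 500, m_snps = 1000, h2 = 0.3,
                    n_causal = 100, seed = 42)
panel <- simulate_panel(cfg)
sim   <- simulate_phenotype(panel, cfg)
study <- gwas_scan(panel, sim$phenotype,
                   study_metadata("demo", "simulated trait", sample_size = 500))

h <- harmonize_study(study, panel)
h$report
#> <harmonization_report>
#>   EXACT                667
#>   AMBIGUOUS_RESOLVED   323
#>   AMBIGUOUS_DROPPED    10
#>   retained 990 / 1000; se recovered 0; eaf filled 0

qc_verdict(h$table, panel)
#> <qc_report>
#>   lambda_GC        1.0500
#>   trait variance   1.0003
#>   effect skewness  0.2520
#>   outliers         0.00% of 990 checked
#>   verdict          recommended
```

667 records already matched the panel orientation; 323 palindromic SNPs
were resolved by frequency and 10 high-MAF palindromic SNPs dropped. The
clean scan passes QC: lambda_GC near 1 (mild polygenic inflation), implied
trait variance ~1 (the simulated phenotype is standardized), no outliers.
Corrupting 15 % of the frequencies flips the verdict:

```r
bad <- corrupt_sumstats(h$table, "af_flip", fraction = 0.15, seed = 1)
qc_verdict(bad, panel)$verdict
#> [1] "not_recommended"
```

A command-line front end wraps the same functions
(`inst/cli/gwaskit convert|harmonize|qc|meta|ldsc|smr|mr|simulate`).

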