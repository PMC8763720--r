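---
title: "Models and methods behind gwaskit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind gwaskit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette documents the statistical models, the tunable parameters and
the design decisions behind the package, in the spirit of the methods
sections of the established summary-statistics toolchains. It states no
empirical result beyond what the test suite and `scripts/acceptance.R`
themselves compute.

## 1. The record model and dialects

The atomic record is one SNP-trait association: identifier, chromosome and
1-based position (VCF convention; the genome build is metadata only — no
liftover), effect and other allele over A/C/G/T, effect-allele frequency,
additive effect `beta`, its standard error, two-sided p-value, z-score and
sample size. Any subset may be missing; harmonization reconstructs what is
derivable. Alleles are uppercased on read; records with alleles outside
A/C/G/T, or with unparseable chromosome/position, are dropped and counted
in the parse report so the harmonization stage remains total. The canonical
missing marker is `NA`; source dialects may declare their own missing codes
(default `NA`, `.`, empty, `NaN`) and a `-log10(p)` p-column, which covers
the common public download formats. Because no fixed list of source
dialects exists, `dialect_spec` is a general mechanism (column map +
delimiter + missing codes) rather than an enumeration.

## 2. Harmonization

The canonical orientation takes the reference panel's alternate allele as
the effect allele. For a record with allele pair (EA, OA) and panel pair
(ref, alt) there are four strand/swap configurations; swaps negate `beta`
and `z` and complement the frequency, strand flips complement the bases.
Palindromic pairs (A/T, C/G) are strand-ambiguous: they are oriented by
whichever of `EAF` and `1 - EAF` is closer to the reference frequency, but
only when both study and reference minor-allele frequencies are below the
ambiguity threshold (default 0.4; configurable). Near 0.5 the frequency
carries no orientation signal, and a wrong call silently negates an effect,
so such records are dropped — the standard practice trade-off.

Records are matched by SNP identifier with chromosome/position as
verification; an identifier match at a discordant position is treated as
absent from the reference. Records absent from the reference are retained
and flagged (`in_reference = FALSE`) rather than dropped: they cannot be
frequency-checked, but remain available to analyses that do not need the
panel.

Field reconstruction uses the normal model throughout:
`z(p) = Phi^{-1}(1 - p/2)` signed by `beta`, `se = |beta|/|z(p)|`
(undefined at `beta = 0` or `p = 1`; left missing and counted), `z =
beta/se` and `p = 2(1 - Phi(|z|))` where missing. P-values below the
smallest positive normal double are clamped with a warning before the
quantile is taken.

## 3. Quality control

Four checks, per the platform design the package implements:

1. **Frequency concordance** — flag when `|EAF - ref_af| > 0.2`.
2. **p/Z concordance** — flag when reported and recomputed p differ by more
   than one decade (`|log10 p_rep - log10 p_comp| > 1`), computed on the
   log scale so genome-wide hits do not underflow.
3. **Effect-size symmetry** — sample skewness `g1 = m3/m2^{3/2}` of `beta`;
   asymmetric when `|g1| > 0.5`. A skewness statistic was chosen because it
   is the simplest scale-free moment test of asymmetry; the cutoff 0.5 is
   far above the sampling noise of a null scan at the sizes involved
   (SD of g1 is about `sqrt(6/m)`).
4. **Study-level statistics** — `lambda_GC = median(z^2)/qchisq(0.5, 1)`
   and the implied trait variance `median(se_j^2 n_j 2 p_j(1-p_j))`, whose
   target is 1 for a standardized phenotype. The median makes the variance
   estimate robust to top hits, where the omitted `beta^2` term is
   non-negligible; the residual bias is O(h2/M) per SNP.

A SNP is an outlier when any per-SNP flag is set; SNPs unchecked by both
per-SNP tests (missing fields, absent from the reference) are excluded from
the denominator. The verdict is **not recommended** exactly when the
outlier fraction strictly exceeds 5 % or the distribution is asymmetric —
the strict inequality is part of the rule, and the boundary behaviour is
tested. The numeric thresholds (0.2 frequency delta, one decade, skewness
0.5) are configurable; the defaults are deliberately loose enough to
tolerate rounding in published files.

## 4. Meta-analysis

Fixed-effect inverse-variance weighting per SNP (`w_i = 1/se_i^2`,
`beta = sum(w b)/sum(w)`, `se = sum(w)^{-1/2}`, Cochran's
`Q = sum w (b - beta)^2`, `I^2 = max(0, 1 - (k-1)/Q)`), and the
sample-size-weighted z-score (Stouffer) method
`z = sum(sqrt(n_i) z_i)/sqrt(sum n_i)`, which yields direction and
significance only. SNPs present in a subset of studies are combined over
that subset with `k_studies` recorded (`--complete-cases` restricts to the
intersection). No genomic-control correction is applied to inputs; per-study
`lambda_GC` is reported by the compatibility checker instead, leaving the
decision to the analyst. Random-effects models are out of scope.

## 5. LD-score regression

Scores are computed from the panel haplotypes:
`l_j = 1 + sum_{k != j, |k-j| <= w} r~^2_{jk}` with the finite-sample
adjustment `r~^2 = r^2 - (1 - r^2)/(n - 2)`, which is unbiased at zero true
correlation — so under linkage equilibrium scores concentrate at 1. The
window is counted in SNPs (default 100) because the synthetic panel has no
genetic map; a base-pair window is available for real panels.

Heritability: regress `chi^2_j = z_j^2` on `x_j = N l_j / M`. Weighting is
two-step: first `1/max(l_j, 1)` (down-weighting over-counted SNPs in LD),
then additionally `1/(2 E[chi^2_j]^2)` with the expectation taken from the
first fit (the variance of a chi-square), floored to keep weights finite.
Standard errors come from a leave-one-block-out jackknife over contiguous
position-sorted blocks, default 20 at desk scale (genome-wide analyses
conventionally use an order of magnitude more; the count is configurable,
and estimates are invariant to input SNP order because blocks are defined
on the sorted map). An `intercept_one` option constrains the intercept for
confounding-free simulations. The test suite exercises parameter recovery
at n = 2000 individuals and m = 2000 SNPs with 200 causal variants.

Genetic correlation regresses `z1_j z2_j` on `sqrt(n1 n2) l_j / M`; the
intercept absorbs sample overlap. The step-two weight denominator
`E[chi1] E[chi2] + E[z1 z2]^2` reduces exactly to the heritability
denominator `2 E[chi]^2` when the two studies coincide, so the
self-correlation of a study is exactly 1. The jackknife recomputes all
three slopes per left-out block, so the reported SE applies to `rg`
itself.

## 6. Colocalization

**SMR.** `t = z1^2 z2^2 / (z1^2 + z2^2)`, referred to the 1-df chi-square
upper tail; `t <= min(z1^2, z2^2)`, approaching the smaller chi-square as
the other signal grows.

**HEIDI.** Tests constancy of the ratio `b_i = z1_i / z2_i` across SNPs in
LD with the instrument. Z-ratios (standardized effects) are used rather
than effect-size ratios, making the statistic unit-free. Deviations
`d_i = b_i - b_top` get a delta-method covariance around the observed
z-values, with `cov(z_i, z_j) = r_ij` from the panel LD and the two traits
independent:
`cov(b_i, b_j) = r_ij / (z2_i z2_j) + z1_i z1_j r_ij / (z2_i^2 z2_j^2)`.
The statistic `T = sum (d_i / sd_i)^2` is a quadratic form; its null
distribution is the weighted chi-square sum with weights from the
eigenvalues of the correlation matrix of the standardized deviations, and
the tail probability is evaluated by seeded Monte Carlo (default 1e5
draws) — simpler and more testable than numerical inversion, and adequate
for p > 1e-5. A near-singular deviation covariance is ridge-regularized
(1e-8 on the diagonal) with a warning. SNP selection keeps exposure
p < 1.6e-4 (|z| about 3.78), r^2 to the instrument in [0.05, 0.9], prunes
mutual r^2 > 0.9 keeping the smaller exposure p, caps at 20 SNPs —
conventional values for this test family, all exposed as arguments. The
default analysis region is +-500 kb around the instrument.

**Theta.** Implemented as the cosine similarity of the two
orientation-harmonized z-profiles, `sum(z1 z2)/sqrt(sum z1^2 sum z2^2)`.
The metric's source description fixes only "similarity of association
profiles"; an LD-whitened variant (`z -> L^{-1} z` with `LL' = R`) may be
intended and would change values in high-LD regions — a documented open
choice. The raw cosine needs no LD information, which is the metric's
stated advantage.

## 7. Mendelian randomization

Instruments are exposure SNPs with `p < 5e-8`, greedily clumped by
ascending p with `r^2 < 0.01` within 500 kb (the platform's selection rules
are not prescribed; these are the community defaults), joined to the
outcome by identifier. Ratio estimates `beta_y/beta_x` carry the
first-order delta SE `se_y/|beta_x|` by default; a `second_order` flag adds
the exposure-noise term `beta_y^2 se_x^2 / beta_x^4`, which matters when
instrument strength is moderate. IVW combines ratios by inverse variance;
Egger regresses `beta_y` on `beta_x` with a free intercept (the pleiotropy
gauge) after re-orienting so all `beta_x >= 0`, which the intercept's
interpretation requires; the weighted median uses inverse-variance weights
with a seeded parametric bootstrap SE (default 1000 draws). All three
estimators coincide when every ratio is equal, and all are invariant to
re-coding any instrument's alleles.

## 8. The synthetic-data generator

Haplotypes follow a first-order Markov copy model: each allele copies its
left neighbour on the same haplotype with probability `ld_rho`, else is
redrawn at the SNP's target frequency, giving geometric r^2 decay. On top
of this, recombination-hotspot LD breaks occur at rate `hotspot_rate`
(default 0.02 per interval), partitioning the chromosome into LD blocks of
geometric length. The breaks matter: without them every SNP sees the same
LD neighbourhood and the LD-score distribution collapses to a point,
leaving the LD-score regression slope unidentified — block-structured LD
heterogeneity is precisely the feature of real genomes that the method
leans on. Target minor-allele frequencies are uniform on `maf_range`
(default 0.05–0.5); realized frequencies are recomputed from the
haplotypes, and panel frequency always equals the haplotype column mean by
construction. Ref/alt alleles are drawn uniformly over distinct base
pairs, palindromic pairs included, as in real panels.

Phenotypes: standardized-genotype effects at `n_causal` uniformly drawn
SNPs, `beta ~ N(0, h2/n_causal)`, environmental noise `N(0, 1 - h2)`, the
sum centered and scaled to sample variance exactly 1 (so the implied
trait-variance QC statistic has a known target), realized heritability
reported. The scan is plain per-SNP least squares on allele dosage with
t-distribution p-values (n - 2 df) and `z` the t-statistic; monomorphic
SNPs yield missing statistics. Corruptions alter exactly
`round(fraction * m)` seeded-randomly chosen records and return the victim
indices. Every generator operation is a pure function of inputs and seed.

What the generator does **not** emulate: coalescent genealogies and
realistic allele-frequency spectra, population structure and relatedness,
imputation noise (INFO), case-control liability traits, and genuine
confounding that would raise the LDSC intercept. Passing tests therefore
demonstrate correctness of the estimators under a clean additive model,
not robustness to those real-data complications.

## 9. Simulation designs used by the validation suite

Chosen once, as the package's own study conditions, and documented here:

- QC verdict boundary: 1,000-SNP study over a 500-individual cohort;
  corruption restricted to SNPs with reference frequency below 0.2 so every
  flip exceeds the 0.2 tolerance, making the corrupted fraction equal the
  outlier fraction exactly.
- LDSC recovery: one panel of 2,000 individuals x 2,000 SNPs
  (`ld_rho = 0.9`, `hotspot_rate = 0.05`), 100 phenotype replicates at
  h2 = 0.5 with 200 causal SNPs, window 100, 20 jackknife blocks, free
  intercept.
- HEIDI calibration: 50-SNP locus (`ld_rho = 0.9`, no hotspots), instrument
  locus explaining 6 % of the exposure and 3 % of the outcome trait at
  n = 2000; the shared-variant null places both effects on one SNP, the
  alternative separates them by five positions (r^2 about 0.35 — moderate
  LD). An LD reference of 500 individuals distinct from both cohorts is
  used, as in practice.
- MR recovery: two 5,000-individual cohorts drawn from one 10,000-person
  population (a shared population is essential: frequencies and hence
  dosage-scale effects must agree between exposure and outcome cohorts),
  10 causal loci at evenly spaced positions with heterogeneous but
  uniformly strong effects (per-SNP variance 1.5–4.5 %), so every
  instrument clears the selection threshold and winner's-curse selection
  bias — a real phenomenon, but not the estimand here — is negligible.
  The second-order ratio SE is used at these instrument strengths.

## 10. Known limitations

Single fixed reference panel (no multi-panel consensus); no
imputation of untyped SNPs; no random-effects meta-analysis or
genomic-control correction of inputs; no partitioned heritability; no
multi-SNP SMR; no multivariable MR or Steiger filtering; the HEIDI tail
probability is Monte Carlo, so extremely small p-values (< 1e-5) are
resolution-limited; the registry is a flat-file store intended for desk
scale, not a database service.
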