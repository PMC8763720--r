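# Synthetic-data generator: LD-structured haplotype panels under a Markov
# copy model, additive polygenic phenotypes with controlled heritability,
# per-SNP linear-regression scans, and targeted data corruptions.

#' Simulation configuration
#'
#' @param n_individuals Number of diploid individuals (2x haplotypes).
#' @param m_snps Number of SNPs.
#' @param ld_rho Adjacent-SNP haplotype copying probability in \[0, 1);
#'   adjacent-SNP correlation is approximately `ld_rho` and r^2 decays
#'   geometrically with distance within an LD block.
#' @param hotspot_rate Per-interval probability of a recombination-hotspot
#'   LD break (copying suppressed between the flanking SNPs), partitioning
#'   the chromosome into LD blocks of geometric length. Gives the
#'   heterogeneous LD-score distribution seen in real genomes.
#' @param maf_range Interval within (0, 0.5\] from which per-SNP target minor
#'   allele frequencies are drawn uniformly.
#' @param h2 Narrow-sense heritability of the simulated phenotype in \[0, 1\].
#' @param n_causal Number of causal SNPs (<= `m_snps`).
#' @param seed Integer seed; every simulation operation is a pure function of
#'   its inputs and this seed.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_individuals, m_snps, ld_rho = 0.5,
                       maf_range = c(0.05, 0.5), h2 = 0.5,
                       n_causal = min(100L, m_snps), hotspot_rate = 0.02,
                       seed = 1L) {
  stopifnot(n_individuals >= 2, m_snps >= 1, ld_rho >= 0, ld_rho < 1,
            length(maf_range) == 2L, maf_range[1] > 0, maf_range[2] <= 0.5,
            maf_range[1] <= maf_range[2], h2 >= 0, h2 <= 1,
            n_causal <= m_snps, n_causal >= 0,
            hotspot_rate >= 0, hotspot_rate < 1)
  structure(list(n_individuals = as.integer(n_individuals),
                 m_snps = as.integer(m_snps), ld_rho = ld_rho,
                 maf_range = maf_range, h2 = h2,
                 n_causal = as.integer(n_causal),
                 hotspot_rate = hotspot_rate, seed = as.integer(seed)),
            class = "sim_config")
}

# Unordered allele pairs for ref/alt assignment (all 12 ordered pairs).
ALLELE_PAIRS <- {
  g <- expand.grid(ref = c("A", "C", "G", "T"), alt = c("A", "C", "G", "T"),
                   stringsAsFactors = FALSE)
  g[g$ref != g$alt, ]
}

#' Simulate an LD-structured haplotype reference panel
#'
#' Haplotypes follow a first-order Markov copy model: the first SNP's allele
#' is Bernoulli(maf_1); each subsequent allele copies the previous SNP's
#' allele on the same haplotype with probability `ld_rho` and is otherwise
#' redrawn Bernoulli(maf_j). This yields approximately geometric r^2 decay
#' with SNP distance. Target frequencies are drawn uniformly from
#' `maf_range`; realized alternate-allele frequencies are recomputed from the
#' haplotypes. All SNPs sit on chromosome "1" at 1 kb spacing; ref/alt
#' alleles are drawn uniformly over distinct base pairs (palindromic pairs
#' included, as in real panels).
#'
#' @param config A [sim_config()].
#' @param seed Seed (defaults to `config$seed`).
#' @return A `reference_panel`.
#' @export
simulate_panel <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  n_hap <- 2L * config$n_individuals
  m <- config$m_snps
  with_seed(seed, {
    maf <- runif(m, config$maf_range[1], config$maf_range[2])
    hotspot <- runif(m) < config$hotspot_rate
    H <- matrix(0L, n_hap, m)
    H[, 1L] <- rbinom(n_hap, 1L, maf[1L])
    if (m > 1L) for (j in 2L:m) {
      rho_j <- if (hotspot[j]) 0 else config$ld_rho
      copy <- rbinom(n_hap, 1L, rho_j) == 1L
      fresh <- rbinom(n_hap, 1L, maf[j])
      H[, j] <- ifelse(copy, H[, j - 1L], fresh)
    }
    pair_idx <- sample.int(nrow(ALLELE_PAIRS), m, replace = TRUE)
    snp_map <- data.frame(snp_id = sprintf("rs%d", seq_len(m)),
                          chrom = "1", pos = 1000L * seq_len(m),
                          ref_allele = ALLELE_PAIRS$ref[pair_idx],
                          alt_allele = ALLELE_PAIRS$alt[pair_idx],
                          stringsAsFactors = FALSE)
    new_reference_panel(snp_map, H)
  })
}

standardize_columns <- function(X) {
  mu <- colMeans(X)
  sdv <- apply(X, 2L, sd)
  poly <- sdv > 0
  Xs <- sweep(X, 2L, mu, "-")
  Xs[, poly] <- sweep(Xs[, poly, drop = FALSE], 2L, sdv[poly], "/")
  Xs[, !poly] <- 0
  list(X = Xs, polymorphic = poly)
}

#' Simulate an additive polygenic phenotype
#'
#' Genotypes are haplotype-pair dosage sums, standardized per SNP. A causal
#' set is drawn uniformly among polymorphic SNPs (monomorphic draws are
#' resampled and counted) unless supplied; causal effects on the
#' standardized-genotype scale are N(0, h2/n_causal); environmental noise is
#' N(0, 1 - h2). The phenotype is centered and scaled to sample variance
#' exactly 1, and the realized heritability var(genetic)/var(phenotype) is
#' reported.
#'
#' @param panel A `reference_panel` (the study cohort's genotypes).
#' @param config A [sim_config()] carrying `h2` and `n_causal`.
#' @param seed Seed (defaults to `config$seed + 1` so the phenotype stream is
#'   distinct from the panel stream under one config).
#' @param causal_indices,causal_betas Optional fixed causal architecture
#'   (standardized scale); both must be given together.
#' @return List with `phenotype` (length-n vector) and `truth` (a
#'   `sim_truth`: `causal_indices`, `causal_betas`, `h2_realized`,
#'   `n_resampled_monomorphic`).
#' @export
simulate_phenotype <- function(panel, config, seed = config$seed + 1L,
                               causal_indices = NULL, causal_betas = NULL) {
  stopifnot(inherits(panel, "reference_panel"), inherits(config, "sim_config"))
  X <- panel_genotypes(panel)
  n <- nrow(X); m <- ncol(X)
  std <- standardize_columns(X)
  with_seed(seed, {
    n_resampled <- 0L
    if (is.null(causal_indices)) {
      pool <- which(std$polymorphic)
      draw <- sample(seq_len(m), config$n_causal)
      bad <- !draw %in% pool
      n_resampled <- sum(bad)
      if (any(bad)) {
        repl <- sample(setdiff(pool, draw), sum(bad))
        draw[bad] <- repl
      }
      causal_indices <- sort(draw)
      causal_betas <- if (config$h2 > 0 && config$n_causal > 0)
        rnorm(length(causal_indices), 0, sqrt(config$h2 / config$n_causal))
      else numeric(length(causal_indices))
    } else {
      stopifnot(!is.null(causal_betas),
                length(causal_betas) == length(causal_indices))
    }
    g <- if (length(causal_indices))
      drop(std$X[, causal_indices, drop = FALSE] %*% causal_betas)
    else rep(0, n)
    e <- rnorm(n, 0, sqrt(max(0, 1 - config$h2)))
    y0 <- g + e
    s <- sd(y0)
    y <- (y0 - mean(y0)) / s
    truth <- structure(list(causal_indices = causal_indices,
                            causal_betas = causal_betas,
                            h2_realized = var(g) / var(y0),
                            n_resampled_monomorphic = n_resampled),
                       class = "sim_truth")
    list(phenotype = y, truth = truth)
  })
}

#' Per-SNP linear-regression association scan
#'
#' Simple least-squares regression of the phenotype on each SNP's allele
#' dosage: beta, se, two-sided p from the t distribution (n - 2 df), z (the
#' t-statistic), eaf and n, assembled into a canonical `sumstats_table`.
#' Monomorphic SNPs get missing statistics.
#'
#' @param panel A `reference_panel` holding the cohort genotypes.
#' @param phenotype Numeric vector, one value per individual.
#' @param metadata Optional [study_metadata()]; a generic record is built if
#'   omitted.
#' @param individuals Optional integer indices restricting the scan to a
#'   sub-cohort.
#' @return A `sumstats_table`.
#' @export
gwas_scan <- function(panel, phenotype, metadata = NULL, individuals = NULL) {
  stopifnot(inherits(panel, "reference_panel"))
  X <- panel_genotypes(panel)
  if (!is.null(individuals)) {
    X <- X[individuals, , drop = FALSE]
    phenotype <- phenotype[individuals]
  }
  n <- nrow(X)
  stopifnot(length(phenotype) == n, n > 2L)
  yc <- phenotype - mean(phenotype)
  xm <- colMeans(X)
  sxx <- colSums(X^2) - n * xm^2
  sxy <- drop(crossprod(X, yc))
  poly <- sxx > 0
  beta <- se <- p <- z <- rep(NA_real_, ncol(X))
  beta[poly] <- sxy[poly] / sxx[poly]
  syy <- sum(yc^2)
  rss <- syy - beta[poly]^2 * sxx[poly]
  rss[rss < 0] <- 0
  sigma2 <- rss / (n - 2L)
  se[poly] <- sqrt(sigma2 / sxx[poly])
  tstat <- beta[poly] / se[poly]
  z[poly] <- tstat
  p[poly] <- 2 * pt(abs(tstat), df = n - 2L, lower.tail = FALSE)
  if (is.null(metadata))
    metadata <- study_metadata(study_id = "simulated_scan",
                               trait_name = "simulated trait",
                               sample_size = n)
  sm <- panel$snp_map
  rec <- data.frame(snp_id = sm$snp_id, chrom = sm$chrom, pos = sm$pos,
                    ea = sm$alt_allele, oa = sm$ref_allele,
                    eaf = xm / 2, beta = beta, se = se, p = p, z = z,
                    n = n, stringsAsFactors = FALSE)
  new_sumstats_table(rec, metadata)
}

CORRUPTION_KINDS <- c("af_flip", "p_scramble", "beta_inflate", "strand_error")

#' Inject targeted corruptions into a summary-statistics table
#'
#' Alters exactly `round(fraction * m)` seeded-randomly chosen records:
#' `af_flip` replaces eaf by 1 - eaf; `p_scramble` permutes p among victims;
#' `beta_inflate` multiplies beta by 10 leaving se; `strand_error` complements
#' both alleles without re-orienting.
#'
#' @param table A `sumstats_table`.
#' @param kind One of `"af_flip"`, `"p_scramble"`, `"beta_inflate"`,
#'   `"strand_error"`.
#' @param fraction Fraction of records to corrupt, in \[0, 1\].
#' @param seed Integer seed selecting the victims.
#' @return The corrupted `sumstats_table`; the `"victims"` attribute holds the
#'   corrupted record indices.
#' @export
corrupt_sumstats <- function(table, kind, fraction, seed = 1L) {
  stopifnot(inherits(table, "sumstats_table"), fraction >= 0, fraction <= 1)
  kind <- match.arg(kind, CORRUPTION_KINDS)
  rec <- table$records
  m <- nrow(rec)
  n_vict <- round(fraction * m)
  victims <- if (n_vict > 0L)
    with_seed(seed, sort(sample.int(m, n_vict))) else integer(0)
  if (n_vict > 0L) switch(kind,
    af_flip = { rec$eaf[victims] <- 1 - rec$eaf[victims] },
    p_scramble = {
      perm <- with_seed(seed + 1L, sample(victims))
      rec$p[victims] <- rec$p[perm]
    },
    beta_inflate = { rec$beta[victims] <- 10 * rec$beta[victims] },
    strand_error = {
      rec$ea[victims] <- complement_alleles(rec$ea[victims])
      rec$oa[victims] <- complement_alleles(rec$oa[victims])
    })
  out <- new_sumstats_table(rec, table$metadata)
  attr(out, "victims") <- victims
  out
}

#' Simulate regional z-score profiles for two traits
#'
#' Draws summary-level z-scores for one locus directly from the multivariate
#' normal implied by the LD matrix: z ~ N(sqrt(n) * R b, R), where R is the
#' signed haplotype correlation of the region and b the causal effects on the
#' standardized scale. Used to study colocalization tests at scale without
#' re-simulating cohorts.
#'
#' @param ld Signed SNP correlation matrix of the region.
#' @param effects1,effects2 Causal effect vectors (standardized scale, length
#'   = region size) for the two traits.
#' @param n1,n2 GWAS sample sizes behind the two z vectors.
#' @param seed Integer seed.
#' @return List with `z1` and `z2`.
#' @export
simulate_region_zscores <- function(ld, effects1, effects2, n1, n2, seed = 1L) {
  m <- nrow(ld)
  stopifnot(length(effects1) == m, length(effects2) == m)
  ev <- eigen(ld, symmetric = TRUE)
  L <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), m)
  with_seed(seed, {
    z1 <- drop(sqrt(n1) * ld %*% effects1 + L %*% rnorm(m))
    z2 <- drop(sqrt(n2) * ld %*% effects2 + L %*% rnorm(m))
    list(z1 = z1, z2 = z2)
  })
}
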