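# Independent brute-force oracles used to freeze expected values.
# These deliberately avoid the code paths they check (direct lchoose /
# log-product arithmetic instead of dhyper / lbeta).

# two-sided Fisher exact p by exhaustive enumeration of the hypergeometric
# support, point-mass-inclusive rule
enum_fisher_p <- function(a, b, c, d) {
  r1 <- a + b
  r2 <- c + d
  k <- a + c
  x <- max(0, k - r2):min(r1, k)
  logp <- lchoose(r1, x) + lchoose(r2, k - x) - lchoose(r1 + r2, k)
  p <- exp(logp)
  p_obs <- p[x == a]
  min(1, sum(p[p <= p_obs * (1 + 1e-07)]))
}

# upper-tail hypergeometric p by enumeration
enum_hyper_upper <- function(k, n_target, n_universe, n_query) {
  x <- k:min(n_target, n_query)
  sum(exp(lchoose(n_target, x) + lchoose(n_universe - n_target, n_query - x) -
            lchoose(n_universe, n_query)))
}

# beta-binomial log pmf via the rising-product route (independent of lbeta)
bb_loglik_oracle <- function(ref, total, mu, rho) {
  a <- mu * (1 - rho) / rho
  b <- (1 - mu) * (1 - rho) / rho
  one <- function(k, n) {
    num_a <- if (k > 0) sum(log(a + 0:(k - 1))) else 0
    num_b <- if (n - k > 0) sum(log(b + 0:(n - k - 1))) else 0
    den <- sum(log(a + b + 0:(n - 1)))
    lchoose(n, k) + num_a + num_b - den
  }
  sum(mapply(one, ref, total))
}

# Spearman rho as rank-then-Pearson
spearman_oracle <- function(x, y) {
  cor(rank(x), rank(y), method = "pearson")
}

# beta-binomial group simulator used by the calibration / power checks
sim_bb_group <- function(n, mu, rho, coverage) {
  tot <- rpois(n, coverage)
  tot[tot == 0] <- 1L
  if (rho == 0) {
    k <- rbinom(n, tot, mu)
  } else {
    a <- mu * (1 - rho) / rho
    b <- (1 - mu) * (1 - rho) / rho
    k <- rbinom(n, tot, rbeta(n, a, b))
  }
  list(ref = k, total = tot)
}

# small cohort shortcut for detection / concordance tests
tiny_cohort <- function(n = 30, genes = 2, seed = 1, ...) {
  simulate_cohort(cohort_spec(n_individuals = n, n_genes = genes,
                              seed = seed, ...))
}

# hand-built single-sample counts + genotypes for exact Fisher checks:
# one gene, one alternative target SNP and one constitutive SNP whose
# haplotype-oriented counts are given directly (phase REF_ON_H1).
single_test_data <- function(target_ref, target_alt, const_h1, const_h2) {
  counts <- tibble::tibble(
    sample_id = "s1",
    snp_id = c("target", "const"),
    chrom = "chr1",
    pos = c(500L, 100L),
    ref_count = c(target_ref, const_h1),
    alt_count = c(target_alt, const_h2),
    gene_id = "g1",
    region_class = c("ALTERNATIVE", "CONSTITUTIVE"),
    event_id = c("ev1", NA)
  )
  genotypes <- tibble::tibble(
    individual_id = "i1",
    snp_id = c("target", "const"),
    a1 = 0L, a2 = 1L, gt = "0|1"
  )
  metadata <- tibble::tibble(sample_id = "s1", individual_id = "i1",
                             region = "r1", group = "AD")
  list(counts = counts, genotypes = genotypes, metadata = metadata)
}
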