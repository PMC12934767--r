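test_that("fisher and hypergeometric agree with tail enumeration", {
  # representative grid of small 2x2 tables
  for (r1 in c(3, 7, 12)) {
    for (r2 in c(4, 9, 12)) {
      for (k in 0:(r1 + r2)) {
        for (a in max(0, k - r2):min(r1, k)) {
          b <- r1 - a
          c <- k - a
          d <- r2 - c
          expect_equal(allelesplice:::fisher2x2_p(a, b, c, d),
                       enum_fisher_p(a, b, c, d), tolerance = 1e-10)
        }
      }
    }
  }
})

test_that("matched backgrounds respect the matching windows", {
  universe <- tibble::tibble(
    gene_id = c("q", "in1", "in2", "edge_lo", "edge_hi", "out1", "out2",
                "asas1"),
    expression = c(100, 95, 105, 90, 110, 89, 100, 100),
    length = c(1000, 950, 1050, 900, 1100, 1000, 1111, 1000),
    is_asas = c(TRUE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, TRUE)
  )
  sets <- matched_background_sets("q", universe, n_sets = 200, seed = 4)
  picked <- unique(unlist(sets))
  # the +/-10% windows are inclusive at both edges
  expect_setequal(picked, c("in1", "in2", "edge_lo", "edge_hi"))
  expect_false(any(c("out1", "out2", "asas1") %in% picked))
})

test_that("matched background sampling is reproducible and never picks ASAS genes", {
  u <- simulate_gene_universe(n_genes = 2000, n_terms = 10, n_query = 30,
                              seed = 2)
  s1 <- matched_background_sets(u$query_genes, u$universe, n_sets = 50,
                                seed = 9)
  s2 <- matched_background_sets(u$query_genes, u$universe, n_sets = 50,
                                seed = 9)
  expect_identical(s1, s2)
  asas <- u$universe$gene_id[u$universe$is_asas]
  expect_false(any(unlist(s1) %in% asas))
  # without replacement within a set
  expect_true(all(vapply(s1, function(s) !anyDuplicated(s), logical(1))))
})

test_that("tolerance widening and degenerate single-match universes work", {
  universe <- tibble::tibble(
    gene_id = c("q", "wide"),
    expression = c(100, 120), # within +/-20%, not +/-10%
    length = c(1000, 1150),
    is_asas = c(TRUE, FALSE)
  )
  sets <- matched_background_sets("q", universe, n_sets = 10, seed = 1)
  expect_true(all(vapply(sets, identical, logical(1), "wide")))

  universe$expression[2] <- 1e6 # beyond +/-25%: dropped with warning
  expect_error(
    expect_warning(matched_background_sets("q", universe, n_sets = 5,
                                           seed = 1), "no matched"),
    "no query gene"
  )
})

test_that("empirical term p-values follow the pseudocount formula", {
  query <- c("g1", "g2", "g3")
  bg <- replicate(100, c("b1", "b2", "b3"), simplify = FALSE)
  ann <- tibble::tibble(
    gene_id = c("g1", "g2", "g3", "b1"),
    term = c("hit", "hit", "hit", "miss")
  )
  enr <- empirical_term_enrichment(query, bg, ann)
  # term in every query gene, never in background: p = 1/(n_sets + 1)
  expect_equal(enr$empirical_p[enr$term == "hit"], 1 / 101)
  # term absent from the query: every background count >= 0 = query count
  expect_equal(enr$empirical_p[enr$term == "miss"], 1)
  expect_true(all(enr$empirical_p >= 1 / 101))
})

test_that("a planted enriched term is detected against matched backgrounds", {
  u <- simulate_gene_universe(n_genes = 4000, n_terms = 40, n_query = 100,
                              seed = 6)
  bg <- suppressWarnings(
    matched_background_sets(u$query_genes, u$universe, n_sets = 500,
                            seed = 6))
  enr <- empirical_term_enrichment(u$query_genes, bg, u$annotations)
  expect_lte(enr$empirical_p[enr$term == u$planted_term], 0.05)
  expect_equal(enr$term[1], u$planted_term) # smallest p overall
})

test_that("hypergeometric overlap matches combinatorial enumeration", {
  # 5 query genes, target contains them all, universe of 10
  query <- sprintf("q%d", 1:5)
  background <- sprintf("b%d", 1:5)
  res <- hypergeometric_overlap(query, query, background)
  expect_equal(res$p_value, 1 / choose(10, 5), tolerance = 1e-12)

  # disjoint target: p = 1
  res2 <- hypergeometric_overlap(query, "elsewhere", background)
  expect_equal(res2$p_value, 1)

  set.seed(12)
  for (i in 1:20) {
    uni <- sprintf("g%d", 1:15)
    q <- sample(uni, 6)
    t <- sample(uni, sample(3:8, 1))
    res3 <- hypergeometric_overlap(q, t, setdiff(uni, q))
    expect_equal(res3$p_value,
                 enum_hyper_upper(length(intersect(q, t)), length(t), 15, 6),
                 tolerance = 1e-10)
  }
})

test_that("LD overlap applies the block and window rules", {
  ld <- tibble::tibble(snp_id = c("a", "g1", "g2", "far"),
                       block_id = c("B1", "B1", "B2", "B1"))
  asas <- tibble::tibble(snp_id = c("a", "nomap"),
                         chrom = "chr1", pos = c(1000000L, 5000000L))
  gwas <- tibble::tibble(
    snp_id = c("g1", "g2", "far", "exact"),
    chrom = "chr1",
    pos = c(1150000L, 1100000L, 1250001L, 5000000L),
    trait = c("t_same_block", "t_other_block", "t_too_far", "t_exact")
  )
  ov <- ld_overlap(asas, gwas, ld, window = 200000)
  ps <- ov$per_snp
  # same block, 150 kb: LD overlap
  expect_true(ps$ld_overlap[ps$snp_id == "a" & ps$trait == "t_same_block"])
  # different block: no pairing at all
  expect_false(any(ps$snp_id == "a" & ps$trait == "t_other_block"))
  # same block but 250 kb away: outside the window
  expect_false(any(ps$snp_id == "a" & ps$trait == "t_too_far" &
                     ps$ld_overlap))
  # SNP absent from the map is a singleton block: only exact-position
  # GWAS SNPs (also unmapped -> same singleton naming never matches a
  # different id), so no LD overlap, but the direct flag still fires
  expect_true(ps$direct[ps$snp_id == "nomap" & ps$trait == "t_exact"])
})

test_that("identical positions count as both direct and LD overlap", {
  ld <- tibble::tibble(snp_id = c("a", "g"), block_id = c("B", "B"))
  asas <- tibble::tibble(snp_id = "a", chrom = "chr2", pos = 500L)
  gwas <- tibble::tibble(snp_id = "g", chrom = "chr2", pos = 500L,
                         trait = "t")
  ov <- ld_overlap(asas, gwas, ld)
  expect_true(ov$per_snp$ld_overlap)
  expect_true(ov$per_snp$direct)
})

test_that("the GWAS enrichment score is the ratio of proportions", {
  res <- gwas_enrichment_score(5, 50, 2, 100)
  expect_equal(res$score, 5)
  expect_equal(res$p_value, enum_fisher_p(5, 45, 2, 98), tolerance = 1e-10)
  expect_equal(gwas_enrichment_score(7, 7, 13, 13)$score, 1)
  # scale invariance
  expect_equal(gwas_enrichment_score(10, 100, 4, 200)$score,
               gwas_enrichment_score(30, 300, 12, 600)$score)
  # continuity handling for an empty background numerator
  res0 <- gwas_enrichment_score(5, 50, 0, 100)
  expect_false(is.na(res0$score))
  expect_match(res0$note, "continuity")
})

test_that("trait categories use keywords, precedence and case folding", {
  labs <- c("Alzheimer's disease (late onset)", "interferon signaling",
            "standing height", "Brain amyloid deposition",
            "PARKINSON disease", "Cytokine levels", "BMI")
  cats <- gwas_trait_category(labs)
  expect_equal(cats[1], "AD_related")
  expect_equal(cats[2], "immune_related")
  expect_equal(cats[3], "other")
  expect_equal(cats[4], "AD_related") # amyloid beats brain by precedence
  expect_equal(cats[5], "brain_related")
  expect_equal(cats[6], "immune_related")
  expect_equal(cats[7], "other")
})

test_that("KS enrichment boundary behaviour is correct", {
  res_same <- ks_pvalue_enrichment(1:10 / 11, 1:10 / 11, seed = 1)
  expect_lt(res_same$statistic, 0.2) # background is a resample of itself

  obs <- seq(0.001, 0.01, length.out = 20)
  pool <- seq(0.5, 0.9, length.out = 200)
  res <- ks_pvalue_enrichment(obs, pool, seed = 2)
  expect_equal(res$statistic, 1)
  expect_lt(res$p_value, 1e-06)
})

test_that("KS p-values are well calibrated under the null", {
  set.seed(33)
  pool <- runif(500)
  ps <- vapply(1:150, function(i) {
    obs <- sample(pool, 40)
    ks_pvalue_enrichment(obs, pool, seed = i)$p_value
  }, numeric(1))
  expect_lt(mean(ps <= 0.05), 0.12)
  expect_gt(mean(ps), 0.3)
})

test_that("resampled effect comparison reaches the minimal exact rank-sum p", {
  obs <- c(10, 11, 12)
  pool <- c(1, 2, 3, 4, 5)
  res <- resampled_effect_comparison(obs, pool, n_iterations = 1, seed = 1)
  # complete separation: one-sided exact p = 1 / C(n1 + n2, n1)
  expect_equal(res$wilcoxon_p, 1 / choose(6, 3), tolerance = 1e-10)
  expect_equal(res$median_percentile, 1)
})

test_that("resampled effect comparison is null-calibrated", {
  set.seed(55)
  pool <- rnorm(400)
  ps <- vapply(1:100, function(i) {
    obs <- sample(pool, 30)
    resampled_effect_comparison(obs, pool, n_iterations = 50,
                                seed = i)$wilcoxon_p
  }, numeric(1))
  expect_lt(mean(ps <= 0.05), 0.12)
})

test_that("resampling fold change recovers planted effect ratios", {
  set.seed(66)
  pool <- abs(rnorm(2000, 1, 0.2))
  same <- resampling_fold_change(sample(pool, 100), pool,
                                 n_iterations = 300, seed = 3)
  expect_lt(abs(same$fold_change - 1), 0.1)

  doubled <- resampling_fold_change(2 * sample(pool, 100), pool,
                                    n_iterations = 300, seed = 3)
  expect_lt(abs(doubled$fold_change - 2), 0.2)
  expect_lt(doubled$mwu_p, 1e-06)
  expect_equal(doubled$empirical_p, 1 / 301)

  r1 <- resampling_fold_change(sample(pool, 50), pool,
                               n_iterations = 100, seed = 5)
  r2 <- resampling_fold_change(sample(pool, 50), pool,
                               n_iterations = 100, seed = 5)
  expect_identical(r1$null_medians, r2$null_medians)

  zero <- resampling_fold_change(c(1, 2), rep(0, 10), n_iterations = 20,
                                 seed = 1)
  expect_true(is.na(zero$fold_change))
  expect_false(zero$fold_change_defined)
})

test_that("direct overlap Fisher test matches the enumeration oracle", {
  mk <- function(n, hits, chrom = "chr1") {
    tibble::tibble(chrom = chrom, pos = seq_len(n) * 10L +
                     ifelse(seq_len(n) <= hits, 0L, 1000000L))
  }
  gwas <- tibble::tibble(chrom = "chr1", pos = seq_len(50) * 10L)
  a <- mk(100, 10)
  b <- mk(100, 1)
  res <- direct_overlap_fisher(a, b, gwas)
  expect_equal(res$p_value, enum_fisher_p(10, 90, 1, 99),
               tolerance = 1e-10)

  res_eq <- direct_overlap_fisher(mk(50, 5), mk(50, 5), gwas)
  expect_equal(res_eq$p_value, 1)

  res_empty <- direct_overlap_fisher(
    a, b, tibble::tibble(chrom = character(), pos = integer()))
  expect_equal(res_empty$p_value, 1)
  expect_equal(res_empty$table[, "overlap"],
               c(asas = 0L, background = 0L))
})
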