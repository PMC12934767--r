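# a two-isoform gene on the plus strand:
#   tx_inc (canonical): exons [0,100) [200,300) [400,500), CDS from 250,
#                       start codon at 250 (inside the cassette exon)
#   tx_skip:            exons [0,100) [400,500), CDS from 420
plus_gene_models <- function() {
  transcript_models(
    transcripts = tibble::tibble(
      transcript_id = c("tx_inc", "tx_skip", "tx_nc"),
      gene_id = "G",
      strand = "+",
      is_canonical = c(TRUE, FALSE, FALSE),
      is_coding = c(TRUE, TRUE, FALSE),
      start_codon = c(250L, 420L, NA)
    ),
    exons = tibble::tibble(
      transcript_id = c(rep("tx_inc", 3), rep("tx_skip", 2), "tx_nc"),
      start = c(0L, 200L, 400L, 0L, 400L, 600L),
      end = c(100L, 300L, 500L, 100L, 500L, 700L)
    ),
    cds = tibble::tibble(
      transcript_id = c("tx_inc", "tx_inc", "tx_skip"),
      start = c(250L, 400L, 420L),
      end = c(300L, 450L, 480L)
    )
  )
}

# the same gene mirrored around coordinate 1000 onto the minus strand
minus_gene_models <- function() {
  m <- plus_gene_models()
  C <- 1000L
  flip_iv <- function(d) {
    tibble::tibble(transcript_id = d$transcript_id,
                   start = C - d$end, end = C - d$start)
  }
  tx <- m$transcripts
  tx$strand <- "-"
  tx$start_codon <- ifelse(is.na(tx$start_codon), NA,
                           C - 1L - tx$start_codon)
  transcript_models(tx, flip_iv(m$exons), flip_iv(m$cds))
}

test_that("transcript_models rejects malformed structures", {
  expect_error(
    transcript_models(
      tibble::tibble(transcript_id = "t", gene_id = "g", strand = "+",
                     is_canonical = TRUE, is_coding = FALSE,
                     start_codon = NA),
      tibble::tibble(transcript_id = "t", start = c(0L, 50L),
                     end = c(100L, 150L))
    ),
    "overlapping exons"
  )
  expect_error(
    transcript_models(
      tibble::tibble(transcript_id = "t", gene_id = "g", strand = "+",
                     is_canonical = TRUE, is_coding = TRUE,
                     start_codon = 10L),
      tibble::tibble(transcript_id = "t", start = 0L, end = 100L),
      tibble::tibble(transcript_id = "t", start = 50L, end = 80L)
    ),
    "start codon outside CDS"
  )
})

test_that("exon classification follows the majority rule with UTR tie-break", {
  m <- plus_gene_models()
  q <- tibble::tibble(
    gene_id = "G",
    start = c(10L, 240L, 200L, 610L, 900L),
    end = c(60L, 300L, 300L, 650L, 950L)
  )
  res <- classify_exon_region(q, m)
  expect_equal(res$region_class[1], "FIVE_UTR") # fully 5' of the CDS
  expect_equal(res$region_class[2], "CDS")      # 10 bp UTR vs 50 bp CDS
  expect_equal(res$region_class[3], "FIVE_UTR") # 50/50 tie favours UTR
  expect_equal(res$region_class[4], "NC_EXON")  # only tx_nc overlaps
  expect_true(is.na(res$region_class[5]))       # no transcript overlaps
  expect_equal(res$reason[5], "no_overlap")

  # deterministic: reclassification yields the same answers
  expect_identical(classify_exon_region(q, m), res)
})

test_that("three-prime UTR and minus-strand classification are correct", {
  m <- plus_gene_models()
  # tx_inc exonic region beyond the CDS end (450): [450, 500) is 3' UTR
  res <- classify_exon_region(
    tibble::tibble(gene_id = "G", start = 460L, end = 500L), m)
  expect_equal(res$region_class, "THREE_UTR")

  # mirrored gene: the mirrored exon must classify identically
  mm <- minus_gene_models()
  res_m <- classify_exon_region(
    tibble::tibble(gene_id = "G", start = 1000L - 500L,
                   end = 1000L - 460L), mm)
  expect_equal(res_m$region_class, "THREE_UTR")
})

test_that("region enrichment agrees with enumeration and detects bias", {
  # identical class proportions: every per-class table is balanced
  res <- region_enrichment(rep(c("FIVE_UTR", "CDS"), c(5, 5)),
                           rep(c("FIVE_UTR", "CDS"), c(50, 50)))
  for (i in seq_len(nrow(res))) {
    expect_equal(res$p_value[i],
                 enum_fisher_p(res$n_asas[i], res$n_asas_other[i],
                               res$n_background[i],
                               res$n_background_other[i]),
                 tolerance = 1e-10)
    expect_gt(res$p_value[i], 0.5)
  }

  # all ASAS exons in the 5' UTR against a uniform background
  res2 <- region_enrichment(
    rep("FIVE_UTR", 20),
    rep(c("FIVE_UTR", "CDS", "THREE_UTR", "NC_EXON"), each = 25))
  expect_lt(res2$p_value[res2$region_class == "FIVE_UTR"], 0.05)

  expect_equal(nrow(region_enrichment(character(), c("CDS"))), 0)
})

test_that("start-codon comparison identifies alternative starts in the exon", {
  m <- plus_gene_models()
  ev <- list(event_id = "ev", exon_start = 200L, exon_end = 300L,
             upstream_flank = 100L, downstream_flank = 400L)
  res <- compare_start_codons(ev, m)
  expect_true(is.na(res$reason))
  expect_equal(res$per_transcript$verdict, "ALTERNATIVE")
  expect_true(res$per_transcript$alt_start_within_exon)
  expect_true(res$any_alternative)
  expect_equal(res$n_inclusion, 1L)
  expect_equal(res$n_skipping, 1L)
})

test_that("identical start codons give a SAME verdict", {
  m <- plus_gene_models()
  # move the inclusion start codon to match the skipping one
  m$transcripts$start_codon[1] <- 420L
  m$cds <- tibble::tibble(transcript_id = c("tx_inc", "tx_skip"),
                          start = c(420L, 420L), end = c(450L, 480L))
  ev <- list(exon_start = 200L, exon_end = 300L,
             upstream_flank = 100L, downstream_flank = 400L)
  res <- compare_start_codons(ev, m)
  expect_equal(res$per_transcript$verdict, "SAME")
  expect_true(is.na(res$per_transcript$alt_start_within_exon))
  expect_false(res$any_alternative)
})

test_that("start-codon verdicts are strand-mirror invariant", {
  res_p <- compare_start_codons(
    list(exon_start = 200L, exon_end = 300L, upstream_flank = 100L,
         downstream_flank = 400L), plus_gene_models())
  res_m <- compare_start_codons(
    list(exon_start = 700L, exon_end = 800L, upstream_flank = 600L,
         downstream_flank = 900L), minus_gene_models())
  expect_equal(res_m$per_transcript$verdict, res_p$per_transcript$verdict)
  expect_equal(res_m$per_transcript$alt_start_within_exon,
               res_p$per_transcript$alt_start_within_exon)
})

test_that("non-coding inclusion isoforms are untestable", {
  m <- plus_gene_models()
  m$transcripts$is_coding[1] <- FALSE
  m$transcripts$start_codon[1] <- NA
  ev <- list(exon_start = 200L, exon_end = 300L,
             upstream_flank = 100L, downstream_flank = 400L)
  res <- compare_start_codons(ev, m)
  expect_equal(res$reason, "missing_isoform_or_start_codon")
})

test_that("GTF import reproduces hand-built transcript models", {
  skip_if_not_installed("rtracklayer")
  gtf <- c(
    "chr1\ttest\ttranscript\t1\t500\t.\t+\t.\tgene_id \"G\"; transcript_id \"tx_inc\"; tag \"Ensembl_canonical\";",
    "chr1\ttest\texon\t1\t100\t.\t+\t.\tgene_id \"G\"; transcript_id \"tx_inc\";",
    "chr1\ttest\texon\t201\t300\t.\t+\t.\tgene_id \"G\"; transcript_id \"tx_inc\";",
    "chr1\ttest\texon\t401\t500\t.\t+\t.\tgene_id \"G\"; transcript_id \"tx_inc\";",
    "chr1\ttest\tCDS\t251\t300\t.\t+\t0\tgene_id \"G\"; transcript_id \"tx_inc\";",
    "chr1\ttest\tCDS\t401\t450\t.\t+\t1\tgene_id \"G\"; transcript_id \"tx_inc\";",
    "chr1\ttest\tstart_codon\t251\t253\t.\t+\t0\tgene_id \"G\"; transcript_id \"tx_inc\";",
    "chr1\ttest\ttranscript\t1\t500\t.\t+\t.\tgene_id \"G\"; transcript_id \"tx_skip\";",
    "chr1\ttest\texon\t1\t100\t.\t+\t.\tgene_id \"G\"; transcript_id \"tx_skip\";",
    "chr1\ttest\texon\t401\t500\t.\t+\t.\tgene_id \"G\"; transcript_id \"tx_skip\";",
    "chr1\ttest\tCDS\t421\t480\t.\t+\t0\tgene_id \"G\"; transcript_id \"tx_skip\";",
    "chr1\ttest\tstart_codon\t421\t423\t.\t+\t0\tgene_id \"G\"; transcript_id \"tx_skip\";"
  )
  path <- withr::local_tempfile(fileext = ".gtf")
  writeLines(gtf, path)
  m <- read_gtf_models(path)
  tx <- m$transcripts[order(m$transcripts$transcript_id), ]
  expect_equal(tx$transcript_id, c("tx_inc", "tx_skip"))
  expect_equal(tx$is_canonical, c(TRUE, FALSE))
  expect_true(all(tx$is_coding))
  expect_equal(tx$start_codon, c(250L, 420L)) # converted to 0-based
  expect_equal(min(m$exons$start), 0L)

  ev <- list(exon_start = 200L, exon_end = 300L,
             upstream_flank = 100L, downstream_flank = 400L)
  res <- compare_start_codons(ev, m)
  expect_equal(res$per_transcript$verdict, "ALTERNATIVE")
  expect_true(res$per_transcript$alt_start_within_exon)
})

test_that("spearman rho equals rank-then-Pearson, ties included", {
  set.seed(91)
  for (i in 1:10) {
    x <- sample(round(rnorm(30, 5, 2)))  # integer values force ties
    y <- round(x + rnorm(30, 0, 2))
    expr <- tibble::tibble(gene_id = "g",
                           !!!setNames(as.list(x + 10), paste0("s", 1:30)))
    prot <- tibble::tibble(gene_id = "g",
                           !!!setNames(as.list(y), paste0("s", 1:30)))
    res <- mrna_protein_correlation(expr, prot, min_pairs = 5)
    expect_equal(res$rho, spearman_oracle(x + 10, y), tolerance = 1e-12)
  }
})

test_that("zero-RPKM samples are removed per gene", {
  x <- c(0, 2:20)
  y <- 1:20
  expr <- tibble::tibble(gene_id = "g",
                         !!!setNames(as.list(x), paste0("s", 1:20)))
  prot <- tibble::tibble(gene_id = "g",
                         !!!setNames(as.list(y), paste0("s", 1:20)))
  res <- mrna_protein_correlation(expr, prot)
  expect_equal(res$n_samples_used, 19L)
  expect_equal(res$rho, 1) # remaining pairs are perfectly monotone
  expect_true(res$significant)
})

test_that("genes with too few usable pairs are untestable", {
  expr <- tibble::tibble(gene_id = "g",
                         !!!setNames(as.list(c(1:5, rep(0, 10))),
                                     paste0("s", 1:15)))
  prot <- tibble::tibble(gene_id = "g",
                         !!!setNames(as.list(1:15), paste0("s", 1:15)))
  res <- mrna_protein_correlation(expr, prot, min_pairs = 10)
  expect_true(is.na(res$rho))
  expect_equal(res$reason_code, "too_few_pairs")
})

test_that("independent expression and protein data are null-calibrated", {
  set.seed(101)
  n_genes <- 300
  n_samp <- 40
  mk <- function() {
    m <- matrix(exp(rnorm(n_genes * n_samp)), n_genes)
    colnames(m) <- paste0("s", seq_len(n_samp))
    dplyr::bind_cols(tibble::tibble(gene_id = paste0("g", seq_len(n_genes))),
                     tibble::as_tibble(m))
  }
  res <- mrna_protein_correlation(mk(), mk())
  expect_lte(mean(res$significant), 0.07)
})

test_that("correlated fraction test matches enumeration on extremes", {
  correlations <- tibble::tibble(
    gene_id = c(paste0("a", 1:20), paste0("b", 1:20)),
    n_samples_used = 20L, rho = 0.5,
    p_value = 0.01, fdr = 0.01,
    significant = rep(c(TRUE, FALSE), each = 20)
  )
  res <- correlated_fraction_test(paste0("a", 1:20), paste0("b", 1:20),
                                  correlations)
  expect_equal(res$fraction_a, 1)
  expect_equal(res$fraction_b, 0)
  expect_equal(res$p_value, enum_fisher_p(20, 0, 0, 20), tolerance = 1e-10)

  expect_warning(
    expect_null(correlated_fraction_test(character(), paste0("b", 1:20),
                                         correlations)),
    "no tested gene"
  )
})
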