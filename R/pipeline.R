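#' Pipeline configuration
#'
#' Collects every tunable threshold of the pipeline with the defaults
#' used throughout the analyses: FDR 0.05, heterozygote and sample
#' fractions 0.10, at least 5 samples per group with a minimum allelic
#' ratio difference of 0.1 at nominal alpha 0.05, a 200 kb LD window,
#' 10,000 matched background sets, 1,000 permutation/resampling
#' iterations, and 100 random distance-profile sets.
#'
#' @param cohort A [cohort_spec()] describing the cohort to simulate, or
#'   NULL to read a previously written cohort from `cohort_dir`.
#' @param cohort_dir Directory holding (or receiving) the cohort files.
#' @param fdr_threshold,het_fraction,sample_fraction,min_per_group,delta_min,alpha,window,n_go_sets,n_permutations,n_fold_iterations,n_random_distance_sets
#'   Statistical thresholds (see Details for defaults).
#' @param min_coverage Minimum coverage per tested SNP (default 20).
#' @param min_stratum_size Minimum individuals per disease stratum
#'   (default 20).
#' @param stages Character vector of stages to run, a subset of
#'   `c("simulate", "detect", "concordance", "differential")`.
#' @param seed Master seed; every stochastic stage derives a child seed
#'   from it.
#' @return A validated list of class `asas_config`.
#' @export
asas_config <- function(cohort = cohort_spec(),
                        cohort_dir = NULL,
                        fdr_threshold = 0.05,
                        het_fraction = 0.10,
                        sample_fraction = 0.10,
                        min_per_group = 5,
                        delta_min = 0.1,
                        alpha = 0.05,
                        window = 200000,
                        n_go_sets = 10000,
                        n_permutations = 1000,
                        n_fold_iterations = 1000,
                        n_random_distance_sets = 100,
                        min_coverage = 20,
                        min_stratum_size = 20,
                        stages = c("simulate", "detect", "concordance",
                                   "differential"),
                        seed = 1) {
  check_number(fdr_threshold, "fdr_threshold", lo = 0, hi = 1)
  check_number(het_fraction, "het_fraction", lo = 0, hi = 1)
  check_number(sample_fraction, "sample_fraction", lo = 0, hi = 1)
  check_number(min_per_group, "min_per_group", lo = 1, integer = TRUE)
  check_number(delta_min, "delta_min", lo = 0, hi = 1)
  check_number(alpha, "alpha", lo = 0, hi = 1)
  check_number(window, "window", lo = 0)
  check_number(n_go_sets, "n_go_sets", lo = 1, integer = TRUE)
  check_number(n_permutations, "n_permutations", lo = 1, integer = TRUE)
  check_number(n_fold_iterations, "n_fold_iterations", lo = 1,
               integer = TRUE)
  check_number(n_random_distance_sets, "n_random_distance_sets", lo = 1,
               integer = TRUE)
  check_number(seed, "seed", integer = TRUE)
  bad <- setdiff(stages, c("simulate", "detect", "concordance",
                           "differential"))
  if (length(bad) > 0) {
    abort(sprintf("unknown stage(s): %s", paste(bad, collapse = ", ")))
  }
  structure(
    list(cohort = cohort, cohort_dir = cohort_dir,
         fdr_threshold = fdr_threshold, het_fraction = het_fraction,
         sample_fraction = sample_fraction, min_per_group = min_per_group,
         delta_min = delta_min, alpha = alpha, window = window,
         n_go_sets = n_go_sets, n_permutations = n_permutations,
         n_fold_iterations = n_fold_iterations,
         n_random_distance_sets = n_random_distance_sets,
         min_coverage = min_coverage,
         min_stratum_size = min_stratum_size,
         stages = stages, seed = as.integer(seed)),
    class = "asas_config"
  )
}

#' Run the ASAS pipeline
#'
#' Executes the enabled stages in dependency order — simulate (or load) a
#' cohort, call per-sample ASAS, run the concordance scan in all three
#' modes, compare disease groups — writing each stage's table to
#' `out_dir` along with the configuration echo and a manifest of file
#' digests and row counts. Identical configuration and seed reproduce
#' every output byte for byte.
#'
#' @param config An [asas_config()].
#' @param out_dir Output directory.
#' @return Invisibly, a list with the in-memory results and the manifest.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "asas_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  results <- list()
  skips <- list()

  # --- cohort ---------------------------------------------------------
  if ("simulate" %in% config$stages) {
    cohort <- simulate_cohort(config$cohort)
    cdir <- if (is.null(config$cohort_dir)) {
      file.path(out_dir, "cohort")
    } else {
      config$cohort_dir
    }
    write_cohort(cohort, cdir)
  } else {
    if (is.null(config$cohort_dir)) {
      abort("stage 'simulate' disabled but no cohort_dir to read from")
    }
    cohort <- read_cohort(config$cohort_dir)
  }
  results$cohort <- cohort

  # --- detection ------------------------------------------------------
  if ("detect" %in% config$stages) {
    calls <- call_asas(cohort$counts, cohort$genotypes, cohort$metadata,
                       min_coverage = config$min_coverage,
                       fdr_threshold = config$fdr_threshold)
    calls <- suppressMessages(filter_hla(calls))
    readr::write_tsv(calls, file.path(out_dir, "asas_calls.tsv"))
    readr::write_tsv(calls %>% filter(.data$significant),
                     file.path(out_dir, "tag_snps.tsv"))
    results$calls <- calls
  } else {
    skips$concordance <- "detection stage disabled"
    skips$differential <- "detection stage disabled"
  }

  # --- concordance ----------------------------------------------------
  if ("concordance" %in% config$stages && !is.null(results$calls)) {
    scans <- purrr::map(c(ALL = "ALL", AD = "AD", CONTROL = "CONTROL"),
      function(m) {
        concordance_scan(
          results$calls, cohort$genotypes, cohort$snp_info,
          cohort$metadata, cohort$events, mode = m,
          het_fraction = config$het_fraction,
          sample_fraction = config$sample_fraction,
          n_permutations = config$n_permutations,
          fdr_threshold = config$fdr_threshold,
          min_stratum_size = config$min_stratum_size,
          seed = child_seed(config$seed, "concordance")
        )
      })
    for (m in names(scans)) {
      readr::write_tsv(scans[[m]],
                       file.path(out_dir,
                                 sprintf("concordance_%s.tsv",
                                         tolower(m))))
    }
    results$concordance <- scans
    if (nrow(scans$AD) > 0 && nrow(scans$CONTROL) > 0) {
      ds <- disease_specific_functional(scans$AD, scans$CONTROL)
      readr::write_tsv(ds, file.path(out_dir, "disease_specific.tsv"))
      results$disease_specific <- ds
    } else {
      skips$disease_specific <- "a disease stratum was skipped"
    }
  } else if ("concordance" %in% config$stages) {
    skips$disease_specific <- "concordance stage unavailable"
  } else {
    skips$disease_specific <- "concordance stage disabled"
  }

  # --- differential ---------------------------------------------------
  if ("differential" %in% config$stages && !is.null(results$calls)) {
    diff <- differential_scan(results$calls, cohort$metadata,
                              min_per_group = config$min_per_group,
                              delta_min = config$delta_min,
                              alpha = config$alpha)
    readr::write_tsv(diff, file.path(out_dir, "differential.tsv"))
    results$differential <- diff
  }

  # --- manifest -------------------------------------------------------
  yaml::write_yaml(config_as_list(config), file.path(out_dir, "config.yml"))
  files <- sort(setdiff(list.files(out_dir, recursive = TRUE),
                        "manifest.json"))
  manifest <- list(
    package = "allelesplice",
    seed = config$seed,
    stages = config$stages,
    skipped = skips,
    files = lapply(files, function(f) {
      path <- file.path(out_dir, f)
      list(file = f,
           md5 = unname(tools::md5sum(path)),
           n_rows = tsv_rows(path))
    })
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  results$manifest <- manifest
  invisible(results)
}

config_as_list <- function(config) {
  out <- unclass(config)
  if (inherits(out$cohort, "cohort_spec")) out$cohort <- unclass(out$cohort)
  out
}

tsv_rows <- function(path) {
  if (!grepl("\\.tsv$", path)) return(NA_integer_)
  length(readr::read_lines(path)) - 1L
}

#' Validate pipeline input files
#'
#' Schema-checks a cohort directory: required files, required columns,
#' coordinate sanity (VCF positions 1-based and positive), zero-coverage
#' count rows, and unphased heterozygous genotypes. Problems are listed
#' in the report, not thrown.
#'
#' @param cohort_dir Directory written by [write_cohort()] (or
#'   hand-assembled in the same layout).
#' @return A tibble report with columns `check`, `status`
#'   (`"ok"`/`"warn"`/`"fail"`), `detail`.
#' @export
validate_inputs <- function(cohort_dir) {
  report <- list()
  note <- function(check, status, detail = "") {
    report[[length(report) + 1L]] <<- tibble(check = check,
                                             status = status,
                                             detail = detail)
  }
  needed <- c("cohort.vcf", "events.tsv", "counts.tsv", "metadata.tsv")
  for (f in needed) {
    p <- file.path(cohort_dir, f)
    if (file.exists(p)) note(paste0("file:", f), "ok")
    else note(paste0("file:", f), "fail", sprintf("missing: %s", p))
  }
  if (any(vapply(report, function(r) r$status == "fail", logical(1)))) {
    return(bind_rows(report))
  }

  counts <- readr::read_tsv(file.path(cohort_dir, "counts.tsv"),
                            show_col_types = FALSE)
  counts_cols <- c("sample_id", "snp_id", "chrom", "pos", "ref_count",
                   "alt_count", "gene_id", "region_class", "event_id")
  missing_cols <- setdiff(counts_cols, names(counts))
  if (length(missing_cols) > 0) {
    note("counts:schema", "fail",
         paste("missing columns:", paste(missing_cols, collapse = ", ")))
  } else {
    note("counts:schema", "ok")
    n_zero <- sum(counts$ref_count + counts$alt_count == 0)
    note("counts:zero_total",
         if (n_zero > 0) "warn" else "ok",
         sprintf("%d rows with zero total (untestable, not fatal)", n_zero))
    bad_event <- sum(
      (counts$region_class == "ALTERNATIVE") != !is.na(counts$event_id))
    note("counts:event_id_iff_alternative",
         if (bad_event > 0) "fail" else "ok",
         sprintf("%d rows violate the event-id rule", bad_event))
  }

  vcf_lines <- readr::read_lines(file.path(cohort_dir, "cohort.vcf"))
  body <- vcf_lines[!startsWith(vcf_lines, "#")]
  pos <- suppressWarnings(
    as.integer(vapply(strsplit(body, "\t"), `[`, "", 2L)))
  note("vcf:positions_1based",
       if (any(is.na(pos) | pos < 1)) "fail" else "ok",
       "VCF POS must be positive integers (converted to 0-based internally)")
  gts <- unlist(lapply(strsplit(body, "\t"), function(x) x[-(1:9)]))
  n_unphased_het <- sum(grepl("/", gts, fixed = TRUE) &
                          vapply(strsplit(gts, "[/|]"),
                                 function(a) a[1] != a[2], logical(1)))
  note("vcf:unphased_het",
       if (n_unphased_het > 0) "warn" else "ok",
       sprintf("%d unphased heterozygous genotypes (excluded from %s)",
               n_unphased_het, "constitutive aggregation"))

  meta <- readr::read_tsv(file.path(cohort_dir, "metadata.tsv"),
                          show_col_types = FALSE)
  meta_cols <- c("sample_id", "individual_id", "region", "group")
  note("metadata:schema",
       if (all(meta_cols %in% names(meta))) "ok" else "fail",
       paste("required:", paste(meta_cols, collapse = ", ")))

  bind_rows(report)
}
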