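#' Write a simulated cohort to disk
#'
#' Emits the cohort as the plain-text formats consumed by the rest of the
#' pipeline: a phased VCF v4.2 (GT with a `|` separator, 1-based
#' positions), and TSV tables for events, allelic counts, sample metadata,
#' SNP annotation, and the simulated truth. A round-trip through
#' [read_cohort()] reproduces the in-memory values exactly.
#'
#' @param cohort An `asas_cohort` from [simulate_cohort()].
#' @param out_dir Output directory (created if absent).
#' @return Invisibly, a tibble manifest of the files written (name, path,
#'   rows, md5 digest).
#' @export
write_cohort <- function(cohort, out_dir) {
  stopifnot(inherits(cohort, "asas_cohort"))
  ok <- dir.exists(out_dir) || dir.create(out_dir, recursive = TRUE,
                                          showWarnings = FALSE)
  if (!ok || !dir.exists(out_dir)) {
    abort(sprintf("cannot create output directory '%s'", out_dir))
  }

  paths <- c(
    vcf = file.path(out_dir, "cohort.vcf"),
    events = file.path(out_dir, "events.tsv"),
    counts = file.path(out_dir, "counts.tsv"),
    metadata = file.path(out_dir, "metadata.tsv"),
    snps = file.path(out_dir, "snps.tsv"),
    truth_functional = file.path(out_dir, "truth_functional.tsv"),
    truth_inclusion = file.path(out_dir, "truth_inclusion.tsv"),
    spec = file.path(out_dir, "spec.yml")
  )

  write_phased_vcf(cohort$genotypes, cohort$snp_info, paths[["vcf"]])
  readr::write_tsv(cohort$events, paths[["events"]])
  readr::write_tsv(cohort$counts, paths[["counts"]])
  readr::write_tsv(cohort$metadata, paths[["metadata"]])
  readr::write_tsv(cohort$snp_info, paths[["snps"]])
  readr::write_tsv(cohort$truth$functional_snps, paths[["truth_functional"]])
  readr::write_tsv(cohort$truth$inclusion, paths[["truth_inclusion"]])
  yaml::write_yaml(unclass(cohort$spec), paths[["spec"]])

  manifest <- tibble(
    name = names(paths),
    path = unname(paths),
    n_rows = vapply(names(paths), function(nm) {
      switch(nm,
        vcf = nrow(cohort$snp_info),
        events = nrow(cohort$events),
        counts = nrow(cohort$counts),
        metadata = nrow(cohort$metadata),
        snps = nrow(cohort$snp_info),
        truth_functional = nrow(cohort$truth$functional_snps),
        truth_inclusion = nrow(cohort$truth$inclusion),
        spec = NA_integer_
      )
    }, integer(1)),
    md5 = unname(tools::md5sum(unname(paths)))
  )
  invisible(manifest)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir Directory containing the cohort files.
#' @return An `asas_cohort` list equivalent to the one written.
#' @export
read_cohort <- function(dir) {
  if (!dir.exists(dir)) abort(sprintf("no such cohort directory '%s'", dir))
  genotypes <- read_phased_vcf(file.path(dir, "cohort.vcf"))
  spec_vals <- yaml::read_yaml(file.path(dir, "spec.yml"))
  spec <- do.call(cohort_spec, spec_vals)
  structure(
    list(
      spec = spec,
      metadata = readr::read_tsv(file.path(dir, "metadata.tsv"),
                                 show_col_types = FALSE),
      events = readr::read_tsv(file.path(dir, "events.tsv"),
                               show_col_types = FALSE),
      snp_info = readr::read_tsv(file.path(dir, "snps.tsv"),
                                 show_col_types = FALSE),
      genotypes = genotypes,
      counts = readr::read_tsv(
        file.path(dir, "counts.tsv"),
        col_types = readr::cols(event_id = readr::col_character(),
                                .default = readr::col_guess())
      ),
      truth = list(
        functional_snps = readr::read_tsv(
          file.path(dir, "truth_functional.tsv"), show_col_types = FALSE),
        inclusion = readr::read_tsv(
          file.path(dir, "truth_inclusion.tsv"), show_col_types = FALSE)
      )
    ),
    class = "asas_cohort"
  )
}

# VCF positions are 1-based; internal coordinates 0-based half-open.
write_phased_vcf <- function(genotypes, snp_info, path) {
  inds <- sort(unique(genotypes$individual_id))
  gt_wide <- genotypes %>%
    select("individual_id", "snp_id", "gt") %>%
    tidyr::pivot_wider(names_from = "individual_id", values_from = "gt")
  snps <- snp_info %>%
    arrange(.data$chrom, .data$pos, .data$snp_id) %>%
    left_join(gt_wide, by = "snp_id")

  header <- c(
    "##fileformat=VCFv4.2",
    "##source=allelesplice",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Phased genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", inds), collapse = "\t")
  )
  body <- apply(snps, 1, function(row) {
    paste(c(row[["chrom"]], as.integer(row[["pos"]]) + 1L, row[["snp_id"]],
            row[["ref"]], row[["alt"]], ".", "PASS", ".", "GT",
            unlist(row[inds], use.names = FALSE)),
          collapse = "\t")
  })
  writeLines(c(header, body), path)
  invisible(path)
}

read_phased_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  snp_ids <- vcfR::getID(v)
  rownames(gt) <- snp_ids
  long <- as_tibble(gt, rownames = "snp_id") %>%
    tidyr::pivot_longer(-"snp_id", names_to = "individual_id",
                        values_to = "gt")
  parts <- strsplit(long$gt, "[/|]")
  a1 <- as.integer(vapply(parts, `[`, "", 1L))
  a2 <- as.integer(vapply(parts, `[`, "", 2L))
  phased <- grepl("\\|", long$gt, fixed = FALSE)
  # unphased heterozygotes have no usable haplotype orientation
  drop <- !phased & !is.na(a1) & !is.na(a2) & a1 != a2
  a1[drop] <- NA_integer_
  a2[drop] <- NA_integer_
  long %>%
    mutate(a1 = a1, a2 = a2) %>%
    select("individual_id", "snp_id", "a1", "a2", "gt") %>%
    arrange(.data$snp_id, .data$individual_id)
}
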