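#' Classify exons into genomic regions
#'
#' Assigns each exon one of `FIVE_UTR`, `CDS`, `THREE_UTR`, `NC_EXON`
#' by overlap with a representative transcript of its gene: the flagged
#' canonical transcript when one overlaps the exon, else the overlapping
#' coding transcript with the longest CDS, else (only non-coding
#' transcripts overlap) `NC_EXON`. Within the representative transcript
#' the class with the largest base overlap wins; ties are broken
#' `FIVE_UTR` > `THREE_UTR` > `CDS`, favouring the untranslated calls the
#' analysis cares about.
#'
#' @param exons Tibble with `gene_id`, `start`, `end` (0-based half-open).
#' @param models A [transcript_models()] object.
#' @return The input with `region_class` and `reason` columns (class is
#'   NA with reason `"no_overlap"` when no transcript of the gene
#'   overlaps the exon).
#' @export
classify_exon_region <- function(exons, models) {
  stopifnot(inherits(models, "transcript_models"))
  tx <- models$transcripts
  ex_by_tx <- split(models$exons, models$exons$transcript_id)
  cds_by_tx <- split(models$cds, models$cds$transcript_id)

  cds_len <- vapply(tx$transcript_id, function(id) {
    ci <- cds_by_tx[[id]]
    if (is.null(ci)) 0L else sum(ci$end - ci$start)
  }, integer(1))
  tx$cds_length <- cds_len

  out <- exons %>%
    mutate(region_class = NA_character_, reason = NA_character_)
  for (i in seq_len(nrow(out))) {
    qs <- out$start[i]
    qe <- out$end[i]
    cand <- tx %>% filter(.data$gene_id == out$gene_id[i])
    overlapping <- cand$transcript_id[vapply(cand$transcript_id,
      function(id) {
        e <- ex_by_tx[[id]]
        !is.null(e) && any(pmin(e$end, qe) > pmax(e$start, qs))
      }, logical(1))]
    if (length(overlapping) == 0) {
      out$reason[i] <- "no_overlap"
      next
    }
    ov <- cand %>% filter(.data$transcript_id %in% overlapping)
    rep_tx <- ov %>% filter(.data$is_canonical, .data$is_coding)
    if (nrow(rep_tx) == 0) {
      rep_tx <- ov %>% filter(.data$is_coding) %>%
        arrange(desc(.data$cds_length), .data$transcript_id)
    }
    if (nrow(rep_tx) == 0) {
      out$region_class[i] <- "NC_EXON"
      next
    }
    rep_tx <- rep_tx[1, ]
    out$region_class[i] <- classify_against_tx(
      qs, qe, rep_tx, ex_by_tx[[rep_tx$transcript_id]],
      cds_by_tx[[rep_tx$transcript_id]]
    )
  }
  out
}

# largest-overlap class within one coding transcript
classify_against_tx <- function(qs, qe, tx_row, tx_exons, tx_cds) {
  cds_min <- min(tx_cds$start)
  cds_max <- max(tx_cds$end)
  ov_len <- function(lo, hi) {
    sum(pmax(0, pmin(tx_exons$end, hi, qe) - pmax(tx_exons$start, lo, qs)))
  }
  if (tx_row$strand == "+") {
    ov5 <- ov_len(-Inf, cds_min)
    ov3 <- ov_len(cds_max, Inf)
  } else {
    ov5 <- ov_len(cds_max, Inf)
    ov3 <- ov_len(-Inf, cds_min)
  }
  ovc <- ov_len(cds_min, cds_max)
  # tie-break favours the UTR classes
  classes <- c(FIVE_UTR = ov5, THREE_UTR = ov3, CDS = ovc)
  names(classes)[which.max(classes)]
}

#' Region-class enrichment of ASAS exons
#'
#' Per-class two-sided Fisher test of ASAS exon classes against a
#' background of annotated exon classes.
#'
#' @param asas_classes,background_classes Character vectors of region
#'   classes (`FIVE_UTR`, `CDS`, `THREE_UTR`, `NC_EXON`).
#' @return A tibble with per-class counts, odds direction and Fisher
#'   `p_value`; empty when `asas_classes` is empty.
#' @export
region_enrichment <- function(asas_classes, background_classes) {
  if (length(asas_classes) == 0) {
    return(tibble(region_class = character(), n_asas = integer(),
                  n_asas_other = integer(), n_background = integer(),
                  n_background_other = integer(), odds_ratio = numeric(),
                  p_value = numeric()))
  }
  classes <- sort(unique(c(asas_classes, background_classes)))
  purrr::map(classes, function(cl) {
    a <- sum(asas_classes == cl)
    b <- length(asas_classes) - a
    c <- sum(background_classes == cl)
    d <- length(background_classes) - c
    tibble(
      region_class = cl, n_asas = a, n_asas_other = b,
      n_background = c, n_background_other = d,
      odds_ratio = (a * d) / pmax(1e-12, b * c),
      p_value = fisher2x2_p(a, b, c, d)
    )
  }) %>% bind_rows()
}

#' Compare start codons between inclusion and skipping isoforms
#'
#' For one splicing event, identifies transcripts that include the event
#' exon (an exon matching its interval exactly) and transcripts that skip
#' it (consecutive exons joining the event's flanking boundaries while
#' omitting the exon), then compares start-codon genomic positions: an
#' inclusion transcript's verdict is `SAME` when its start codon
#' coincides with that of at least one skipping transcript, otherwise
#' `ALTERNATIVE`, in which case the start codon is additionally located
#' relative to the event exon. Transcripts overlapping the exon only
#' partially are ignored (counted).
#'
#' @param event One-row tibble or list with `exon_start`, `exon_end`,
#'   `upstream_flank` (end of the upstream flanking exon) and
#'   `downstream_flank` (start of the downstream flanking exon), plus
#'   `event_id`/`gene_id` if available.
#' @param models A [transcript_models()] object.
#' @return A list of class `start_codon_comparison`: `per_transcript`
#'   (verdict per inclusion transcript), `any_alternative`,
#'   `n_partial_ignored`, and `reason` (non-NA when untestable).
#' @export
compare_start_codons <- function(event, models) {
  stopifnot(inherits(models, "transcript_models"))
  qs <- event$exon_start
  qe <- event$exon_end
  up_end <- event$upstream_flank
  down_start <- event$downstream_flank

  ex_by_tx <- split(models$exons, models$exons$transcript_id)
  inclusion <- character()
  skipping <- character()
  n_partial <- 0L
  for (id in names(ex_by_tx)) {
    e <- ex_by_tx[[id]] %>% arrange(.data$start)
    exact <- any(e$start == qs & e$end == qe)
    if (exact) {
      inclusion <- c(inclusion, id)
      next
    }
    joins <- which(e$end[-nrow(e)] == up_end &
                     e$start[-1] == down_start)
    if (nrow(e) >= 2 && length(joins) > 0) {
      skipping <- c(skipping, id)
      next
    }
    if (any(pmin(e$end, qe) > pmax(e$start, qs))) n_partial <- n_partial + 1L
  }

  tx <- models$transcripts
  inc_tx <- tx %>% filter(.data$transcript_id %in% inclusion,
                          .data$is_coding, !is.na(.data$start_codon))
  skip_tx <- tx %>% filter(.data$transcript_id %in% skipping,
                           .data$is_coding, !is.na(.data$start_codon))

  if (nrow(inc_tx) == 0 || nrow(skip_tx) == 0) {
    return(structure(
      list(per_transcript = tibble(transcript_id = character(),
                                   start_codon = integer(),
                                   verdict = character(),
                                   alt_start_within_exon = logical()),
           any_alternative = NA,
           n_inclusion = nrow(inc_tx), n_skipping = nrow(skip_tx),
           n_partial_ignored = n_partial,
           reason = "missing_isoform_or_start_codon"),
      class = "start_codon_comparison"
    ))
  }

  per_tx <- inc_tx %>%
    mutate(
      verdict = ifelse(.data$start_codon %in% skip_tx$start_codon,
                       "SAME", "ALTERNATIVE"),
      alt_start_within_exon = ifelse(
        .data$verdict == "ALTERNATIVE",
        .data$start_codon >= qs & .data$start_codon < qe,
        NA
      )
    ) %>%
    select("transcript_id", "start_codon", "verdict",
           "alt_start_within_exon")

  structure(
    list(per_transcript = per_tx,
         any_alternative = any(per_tx$verdict == "ALTERNATIVE"),
         n_inclusion = nrow(inc_tx), n_skipping = nrow(skip_tx),
         n_partial_ignored = n_partial,
         reason = NA_character_),
    class = "start_codon_comparison"
  )
}
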