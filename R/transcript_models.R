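#' Transcript model container
#'
#' Holds transcript structures (exons, CDS, start codons) for the
#' annotation-level analyses. All coordinates are 0-based half-open.
#'
#' @param transcripts Tibble: `transcript_id`, `gene_id`, `strand`
#'   (`"+"`/`"-"`), `is_canonical`, `is_coding`, `start_codon` (genomic
#'   position of the first base of the start codon in transcript
#'   orientation; NA when absent).
#' @param exons Tibble: `transcript_id`, `start`, `end`.
#' @param cds Tibble: `transcript_id`, `start`, `end` (may be empty).
#' @return A validated list of class `transcript_models`.
#' @export
transcript_models <- function(transcripts, exons, cds = NULL) {
  if (is.null(cds)) {
    cds <- tibble(transcript_id = character(), start = integer(),
                  end = integer())
  }
  stopifnot(
    all(c("transcript_id", "gene_id", "strand", "is_canonical",
          "is_coding", "start_codon") %in% names(transcripts)),
    all(c("transcript_id", "start", "end") %in% names(exons)),
    all(exons$end > exons$start)
  )
  # exons of one transcript must be sorted and non-overlapping
  bad <- exons %>%
    arrange(.data$transcript_id, .data$start) %>%
    group_by(.data$transcript_id) %>%
    mutate(prev_end = dplyr::lag(.data$end)) %>%
    filter(!is.na(.data$prev_end), .data$prev_end > .data$start) %>%
    ungroup()
  if (nrow(bad) > 0) {
    abort(sprintf("overlapping exons in transcript(s): %s",
                  paste(unique(bad$transcript_id), collapse = ", ")))
  }
  # an annotated start codon must fall inside a CDS interval
  sc <- transcripts %>% filter(!is.na(.data$start_codon))
  if (nrow(sc) > 0 && nrow(cds) > 0) {
    ok <- vapply(seq_len(nrow(sc)), function(i) {
      ci <- cds %>% filter(.data$transcript_id == sc$transcript_id[i])
      nrow(ci) == 0 ||
        any(sc$start_codon[i] >= ci$start & sc$start_codon[i] < ci$end)
    }, logical(1))
    if (!all(ok)) {
      abort(sprintf("start codon outside CDS for: %s",
                    paste(sc$transcript_id[!ok], collapse = ", ")))
    }
  }
  structure(
    list(transcripts = as_tibble(transcripts),
         exons = exons %>% arrange(.data$transcript_id, .data$start),
         cds = cds %>% arrange(.data$transcript_id, .data$start)),
    class = "transcript_models"
  )
}

#' Read transcript models from a GENCODE-style GTF
#'
#' Imports exon, CDS and start_codon features and derives per-transcript
#' canonical/coding flags. Requires the `rtracklayer` package. GTF
#' coordinates (1-based closed) are converted to the package's 0-based
#' half-open convention.
#'
#' @param path Path to a GTF file.
#' @return A `transcript_models` object.
#' @export
read_gtf_models <- function(path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    abort("read_gtf_models() requires the rtracklayer package")
  }
  gr <- rtracklayer::import(path, format = "gtf")
  df <- as_tibble(as.data.frame(gr))
  df$start0 <- df$start - 1L
  df$end0 <- df$end

  ex <- df %>% filter(.data$type == "exon")
  cds <- df %>% filter(.data$type == "CDS")
  sc <- df %>% filter(.data$type == "start_codon")

  tag_col <- if ("tag" %in% names(df)) df$tag else NULL
  tx <- ex %>%
    group_by(.data$transcript_id) %>%
    summarise(gene_id = first(.data$gene_id),
              strand = as.character(first(.data$strand)),
              .groups = "drop")
  canon <- df %>%
    filter(.data$type == "transcript") %>%
    mutate(is_canonical = if ("tag" %in% names(df)) {
      unname(vapply(.data$tag, function(t) {
        any(grepl("canonical", unlist(t), ignore.case = TRUE))
      }, logical(1)))
    } else FALSE) %>%
    select("transcript_id", "is_canonical")
  sc_pos <- sc %>%
    group_by(.data$transcript_id) %>%
    summarise(
      start_codon = if (as.character(first(.data$strand)) == "+") {
        min(.data$start0)
      } else {
        max(.data$end0) - 1L
      },
      .groups = "drop"
    )
  tx <- tx %>%
    left_join(canon, by = "transcript_id") %>%
    left_join(sc_pos, by = "transcript_id") %>%
    mutate(
      is_canonical = !is.na(.data$is_canonical) & .data$is_canonical,
      is_coding = .data$transcript_id %in% cds$transcript_id
    )
  transcript_models(
    transcripts = tx %>%
      select("transcript_id", "gene_id", "strand", "is_canonical",
             "is_coding", "start_codon"),
    exons = ex %>% select("transcript_id", start = "start0", end = "end0"),
    cds = cds %>% select("transcript_id", start = "start0", end = "end0")
  )
}
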