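# Expressed-miRNA filtering and 3-of-5 consensus target voting.
#
# The vote is taken at (miRNA, transcript) granularity: an interaction is
# accepted when at least `min_support` distinct tools report the pair at
# least once. Site coordinates are taken exclusively from the designated
# site-defining tool (the miRanda analog); other tools contribute votes only.
# Pairs that pass the vote but have no site in the site tool cannot be
# intersected with variants and are dropped (their count is reported).

#' Filter miRNAs by expression read count
#'
#' Keeps accessions whose read count is *strictly* greater than
#' `min_readcount` (default 5).
#'
#' @param mirnas tibble with columns accession, read_count.
#' @param min_readcount expression threshold (exclusive).
#' @return character vector of accessions.
#' @export
filter_expressed_mirnas <- function(mirnas, min_readcount = 5) {
  stopifnot(all(mirnas$read_count >= 0))
  mirnas$accession[mirnas$read_count > min_readcount]
}

#' Consensus vote over per-tool target predictions
#'
#' @param predictions tibble (tool, mirna, transcript_id, utr_start, utr_end,
#'   score) as returned by [load_prediction_tables()].
#' @param expressed character vector of expressed miRNA accessions; only
#'   predictions for these miRNAs enter the vote.
#' @param min_support minimum number of distinct supporting tools (default 3).
#' @param site_tool name of the site-defining tool.
#' @param roster tool roster (defaults to the `roster` attribute of
#'   `predictions`, else the tools present). `min_support` may not exceed the
#'   roster size.
#' @return list with class `consensus_interactions`:
#'   * `pairs`: tibble (mirna, transcript_id, support, n_sites)
#'   * `sites`: tibble (mirna, transcript_id, utr_start, utr_end), overlapping
#'     site intervals merged per pair
#'   * `dropped_no_site`: number of pairs passing the vote without a site in
#'     the site tool
#' @export
consensus_vote <- function(predictions, expressed, min_support = 3,
                           site_tool = "miranda", roster = NULL) {
  roster <- roster %||% attr(predictions, "roster") %||%
    unique(predictions$tool)
  if (!site_tool %in% roster) {
    stop_ctx("site_tool '%s' is not in the tool roster", site_tool)
  }
  if (min_support > length(roster)) {
    stop_ctx("min_support (%d) exceeds tool roster size (%d)",
             min_support, length(roster))
  }
  preds <- predictions[predictions$mirna %in% expressed, , drop = FALSE]
  support <- preds |>
    distinct(.data$tool, .data$mirna, .data$transcript_id) |>
    dplyr::count(.data$mirna, .data$transcript_id, name = "support") |>
    filter(.data$support >= min_support)

  site_preds <- preds |>
    filter(.data$tool == site_tool) |>
    semi_join(support, by = c("mirna", "transcript_id"))

  # merge overlapping site intervals by union, per pair
  sites <- merge_sites(site_preds)

  with_sites <- distinct(sites, .data$mirna, .data$transcript_id)
  dropped <- nrow(anti_join(support, with_sites,
                            by = c("mirna", "transcript_id")))
  pairs <- support |>
    inner_join(dplyr::count(sites, .data$mirna, .data$transcript_id,
                            name = "n_sites"),
               by = c("mirna", "transcript_id")) |>
    arrange(.data$mirna, .data$transcript_id)

  structure(list(pairs = pairs, sites = sites, dropped_no_site = dropped),
            class = "consensus_interactions")
}

merge_sites <- function(site_preds) {
  if (!nrow(site_preds)) {
    return(tibble(mirna = character(), transcript_id = character(),
                  utr_start = integer(), utr_end = integer()))
  }
  key <- paste(site_preds$mirna, site_preds$transcript_id, sep = "\r")
  ir <- IRanges::IRanges(start = site_preds$utr_start + 1L,
                         end = site_preds$utr_end)
  red <- IRanges::reduce(S4Vectors::split(ir, key))
  flat <- unlist(red, use.names = FALSE)
  keys <- rep(names(red), lengths(red))
  parts <- strsplit(keys, "\r", fixed = TRUE)
  tibble(
    mirna = vapply(parts, `[`, character(1), 1),
    transcript_id = vapply(parts, `[`, character(1), 2),
    utr_start = IRanges::start(flat) - 1L,
    utr_end = IRanges::end(flat)
  ) |> arrange(.data$mirna, .data$transcript_id, .data$utr_start)
}

#' @export
print.consensus_interactions <- function(x, ...) {
  cat("consensus interactions:", nrow(x$pairs), "pairs,",
      nrow(x$sites), "merged sites,",
      x$dropped_no_site, "pair(s) dropped without a site-tool site\n")
  invisible(x)
}

#' Flag experimentally validated interactions
#'
#' Sets `validated` true for pairs whose (miRNA, gene-of-transcript) appears
#' in a TarBase/miRTarBase-style validation table.
#'
#' @param consensus a `consensus_interactions` object.
#' @param validated_pairs tibble (mirna, gene_id).
#' @param transcripts `transcript_models` (maps transcript to gene).
#' @return the object with a `validated` column added to `$pairs`.
#' @export
attach_validation <- function(consensus, validated_pairs, transcripts) {
  tx2gene <- transcripts[, c("transcript_id", "gene_id")]
  p <- left_join(consensus$pairs, tx2gene, by = "transcript_id")
  if (nrow(validated_pairs)) {
    vkey <- paste(validated_pairs$mirna, validated_pairs$gene_id)
    p$validated <- paste(p$mirna, p$gene_id) %in% vkey
  } else {
    p$validated <- FALSE
  }
  consensus$pairs <- p
  consensus
}
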