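# Tissue-wise differential-expression filtering, gene-to-QTL assignment and
# Venn-style overlap counts.
#
# Thresholds follow the array analysis they summarise: p <= 0.05 and
# |log2 fold change| >= 0.7, both inclusive; only up-regulated targets are
# carried forward, because losing a miRNA site is expected to raise target
# expression. QTL significance uses LOD strictly above 3.

#' Filter differentially expressed genes per tissue
#'
#' A gene is kept iff pvalue <= `p_max` AND |log2fc| >= `min_abs_log2fc`
#' (both inclusive) AND the fold change has the requested sign.
#'
#' @param expression tibble (gene_id, tissue, log2fc, pvalue).
#' @param p_max inclusive p-value ceiling.
#' @param min_abs_log2fc inclusive absolute log2 fold-change floor.
#' @param direction one of "up", "down", "both".
#' @return tibble (tissue, gene_id); filter parameters are attached as the
#'   `provenance` attribute.
#' @export
filter_upregulated <- function(expression, p_max = 0.05,
                               min_abs_log2fc = 0.7,
                               direction = c("up", "down", "both")) {
  direction <- match.arg(direction)
  keep <- expression$pvalue <= p_max &
    abs(expression$log2fc) >= min_abs_log2fc &
    switch(direction,
           up = expression$log2fc > 0,
           down = expression$log2fc < 0,
           both = TRUE)
  out <- expression[keep, c("tissue", "gene_id")] |>
    distinct() |>
    arrange(.data$tissue, .data$gene_id)
  attr(out, "provenance") <- list(p_max = p_max,
                                  min_abs_log2fc = min_abs_log2fc,
                                  direction = direction)
  out
}

#' Keep QTL with significant linkage (LOD strictly above the threshold)
#' @param qtls QTL tibble. @param lod_min exclusive LOD threshold (default 3).
#' @return filtered tibble.
#' @export
significant_qtl <- function(qtls, lod_min = 3) {
  qtls[qtls$lod > lod_min, , drop = FALSE]
}

#' Assign genes to QTL by any-overlap of the gene body
#'
#' A gene is in a QTL iff its body interval overlaps the QTL interval by at
#' least one base (half-open arithmetic: abutting intervals do not overlap).
#'
#' @param gene_bodies tibble (gene_id, chrom, start, end), 0-based half-open.
#' @param qtls QTL tibble (pre-filtered with [significant_qtl()] if desired).
#' @return tibble (gene_id, qtl_ids = comma-joined overlapped QTL, in_qtl).
#' @export
assign_genes_to_qtl <- function(gene_bodies, qtls) {
  out <- tibble(gene_id = gene_bodies$gene_id,
                qtl_ids = "", in_qtl = FALSE)
  if (nrow(qtls) && nrow(gene_bodies)) {
    g <- granges0(gene_bodies$chrom, gene_bodies$start, gene_bodies$end)
    q <- granges0(qtls$chrom, qtls$start, qtls$end)
    ov <- GenomicRanges::findOverlaps(g, q, ignore.strand = TRUE)
    if (length(ov)) {
      hits <- tapply(qtls$qtl_id[S4Vectors::subjectHits(ov)],
                     S4Vectors::queryHits(ov),
                     function(x) paste(sort(unique(x)), collapse = ","))
      idx <- as.integer(names(hits))
      out$qtl_ids[idx] <- unname(hits)
      out$in_qtl[idx] <- TRUE
    }
  }
  out
}

#' Exclusive Venn-region counts over named gene sets
#'
#' Tallies the 2^k - 1 exclusive membership regions of k sets; the counts
#' partition the union (they sum to its size).
#'
#' @param sets named list of character vectors.
#' @return tibble (region, count) where `region` joins member set names with
#'   "&"; regions with zero elements are included.
#' @export
overlap_counts <- function(sets) {
  stopifnot(length(sets) >= 1, !is.null(names(sets)), all(nzchar(names(sets))))
  k <- length(sets)
  universe <- unique(unlist(sets, use.names = FALSE))
  member <- vapply(sets, function(s) universe %in% s,
                   logical(length(universe)))
  member <- matrix(member, nrow = length(universe), ncol = k,
                   dimnames = list(NULL, names(sets)))
  combos <- expand.grid(rep(list(c(FALSE, TRUE)), k))[-1, , drop = FALSE]
  region <- apply(combos, 1, function(m) paste(names(sets)[unlist(m)],
                                               collapse = "&"))
  sig <- apply(member, 1, function(m) paste(names(sets)[m], collapse = "&"))
  cnt <- table(sig)
  tibble(region = region,
         count = as.integer(ifelse(region %in% names(cnt),
                                   cnt[region], 0L)))
}
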