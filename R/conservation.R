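# Cross-species (mouse <-> human) miRNA conservation and translation of
# impaired interactions.
#
# A mouse miRNA is considered conserved when (i) a local (Smith-Waterman)
# alignment of the mature sequences reaches a minimum score and (ii) the
# 7mer seed (positions 2-8 from the 5' end) is identical. The alignment uses
# linear gap costs (match +1, mismatch -1, gap -2) and a deterministic
# traceback (tie order: diagonal > up > left, best cell chosen at the
# smallest row, then column). The accept decision rests primarily on seed
# identity; the score acts as a loose sanity bound on overall similarity.

#' Smith-Waterman local alignment of two short RNA sequences
#'
#' @param seq_a,seq_b RNA/DNA strings (T is normalised to U); length >= 1,
#'   empty sequences are an error.
#' @param match,mismatch,gap scoring parameters (linear gap cost).
#' @return one-row tibble: score, a_start/a_end and b_start/b_end (1-based
#'   inclusive spans of the aligned region), length (alignment columns),
#'   identity (matches / columns).
#' @export
local_align <- function(seq_a, seq_b, match = 1, mismatch = -1, gap = -2) {
  a <- strsplit(norm_rna(seq_a), "", fixed = TRUE)[[1]]
  b <- strsplit(norm_rna(seq_b), "", fixed = TRUE)[[1]]
  n <- length(a); m <- length(b)
  if (n == 0 || m == 0) stop_ctx("local_align: empty sequence")
  H <- matrix(0, n + 1, m + 1)
  for (i in seq_len(n)) {
    s <- ifelse(a[i] == b, match, mismatch)
    for (j in seq_len(m)) {
      H[i + 1, j + 1] <- max(0,
                             H[i, j] + s[j],
                             H[i, j + 1] + gap,
                             H[i + 1, j] + gap)
    }
  }
  best <- max(H)
  if (best == 0) {
    return(tibble(score = 0, a_start = NA_integer_, a_end = NA_integer_,
                  b_start = NA_integer_, b_end = NA_integer_,
                  length = 0L, identity = NaN))
  }
  hit <- which(H == best, arr.ind = TRUE)
  hit <- hit[order(hit[, 1], hit[, 2]), , drop = FALSE][1, ]
  i <- unname(hit[1]) - 1L; j <- unname(hit[2]) - 1L
  a_end <- i; b_end <- j
  cols <- 0L; matches <- 0L
  while (i > 0 && j > 0 && H[i + 1, j + 1] > 0) {
    s <- if (a[i] == b[j]) match else mismatch
    if (H[i + 1, j + 1] == H[i, j] + s) {
      matches <- matches + (a[i] == b[j])
      i <- i - 1L; j <- j - 1L
    } else if (H[i + 1, j + 1] == H[i, j + 1] + gap) {
      i <- i - 1L
    } else {
      j <- j - 1L
    }
    cols <- cols + 1L
  }
  tibble(score = best, a_start = i + 1L, a_end = a_end,
         b_start = j + 1L, b_end = b_end,
         length = cols, identity = matches / cols)
}

#' Is the 7mer seed conserved between two mature miRNA sequences?
#'
#' True iff positions 2-8 (1-based from the 5' end) are identical after U/T
#' normalisation. Both sequences must be at least 8 nt.
#' @param mouse_seq,human_seq mature sequences.
#' @return logical.
#' @export
seed_conserved <- function(mouse_seq, human_seq) {
  if (nchar(mouse_seq) < 8 || nchar(human_seq) < 8) {
    stop_ctx("seed_conserved: sequences must be >= 8 nt")
  }
  substr(norm_rna(mouse_seq), 2, 8) == substr(norm_rna(human_seq), 2, 8)
}

seed7 <- function(seq) substr(norm_rna(seq), 2, 8)

#' All-vs-all cross-species matching of mature miRNAs
#'
#' A (mouse, human) pair is accepted iff the local-alignment score reaches
#' `min_score` and (when `require_seed`) the 7mer seed is identical. Each
#' mouse miRNA keeps all accepted human partners (miRNA families share
#' seeds, so many-to-many matches are expected).
#'
#' @param mouse,human tibbles with columns accession, name, mature_seq.
#' @param min_score minimum alignment score (default 14, i.e. roughly 70%
#'   identity on a 22-mer under the +1/-1/-2 scoring).
#' @param require_seed require exact seed identity (default TRUE).
#' @param match,mismatch,gap alignment scoring parameters.
#' @return tibble of accepted alignments: mouse_acc, mouse_name, human_acc,
#'   human_name, score, identity, seed_conserved (all TRUE when
#'   `require_seed`).
#' @export
match_mirnas_cross_species <- function(mouse, human, min_score = 14,
                                       require_seed = TRUE,
                                       match = 1, mismatch = -1, gap = -2) {
  empty <- tibble(mouse_acc = character(), mouse_name = character(),
                  human_acc = character(), human_name = character(),
                  score = numeric(), identity = numeric(),
                  seed_conserved = logical())
  if (!nrow(mouse) || !nrow(human)) return(empty)
  pairs <- expand.grid(mi = seq_len(nrow(mouse)), hi = seq_len(nrow(human)))
  if (require_seed) {
    # seed identity is cheap; only seed-conserved pairs can be accepted
    keep <- seed7(mouse$mature_seq[pairs$mi]) ==
      seed7(human$mature_seq[pairs$hi])
    pairs <- pairs[keep, , drop = FALSE]
  }
  if (!nrow(pairs)) return(empty)
  rows <- lapply(seq_len(nrow(pairs)), function(k) {
    mi <- pairs$mi[k]; hi <- pairs$hi[k]
    al <- local_align(mouse$mature_seq[mi], human$mature_seq[hi],
                      match = match, mismatch = mismatch, gap = gap)
    tibble(mouse_acc = mouse$accession[mi], mouse_name = mouse$name[mi],
           human_acc = human$accession[hi], human_name = human$name[hi],
           score = al$score, identity = al$identity,
           seed_conserved = seed_conserved(mouse$mature_seq[mi],
                                           human$mature_seq[hi]))
  })
  out <- bind_rows(rows)
  out <- out[out$score >= min_score &
               (!require_seed | out$seed_conserved), , drop = FALSE]
  arrange(out, .data$mouse_acc, .data$human_acc)
}

#' Mouse impaired interactions conserved in human
#'
#' Emits a record for every mouse site-variant interaction whose target gene
#' has a human ortholog, whose miRNA has an accepted human partner, and for
#' which a MirSNP-style record pairs that human gene with that human miRNA
#' (conjunctive rule: all three are required). Records are deduplicated on
#' (mouse miRNA, human miRNA, mouse gene, human variant).
#'
#' @param mouse_hits tibble (mirna, gene_id, tissues) — one row per impaired
#'   interaction, `tissues` a comma-joined list of tissues where the target
#'   is up-regulated.
#' @param orthologs tibble (mouse_gene, human_gene); many-to-many allowed.
#' @param alignments accepted alignments from [match_mirnas_cross_species()].
#' @param mirsnp tibble (variant_id, human_gene, human_mirna, effect_class);
#'   `human_mirna` matches the alignment's `human_name`.
#' @return tibble: mouse_mirna, human_mirna, mouse_gene, human_gene,
#'   variant_id, effect_class, tissues.
#' @export
conserved_impaired_interactions <- function(mouse_hits, orthologs,
                                            alignments, mirsnp) {
  empty <- tibble(mouse_mirna = character(), human_mirna = character(),
                  mouse_gene = character(), human_gene = character(),
                  variant_id = character(), effect_class = character(),
                  tissues = character())
  if (!nrow(mouse_hits) || !nrow(orthologs) || !nrow(alignments) ||
      !nrow(mirsnp)) return(empty)
  out <- mouse_hits |>
    inner_join(orthologs, by = c(gene_id = "mouse_gene"),
               relationship = "many-to-many") |>
    inner_join(alignments[, c("mouse_acc", "human_name")],
               by = c(mirna = "mouse_acc"), relationship = "many-to-many") |>
    inner_join(mirsnp, by = c(human_gene = "human_gene",
                              human_name = "human_mirna"),
               relationship = "many-to-many") |>
    distinct(.data$mirna, .data$human_name, .data$gene_id, .data$human_gene,
             .data$variant_id, .keep_all = TRUE)
  tibble(mouse_mirna = out$mirna, human_mirna = out$human_name,
         mouse_gene = out$gene_id, human_gene = out$human_gene,
         variant_id = out$variant_id, effect_class = out$effect_class,
         tissues = out$tissues) |>
    arrange(.data$mouse_mirna, .data$mouse_gene, .data$variant_id)
}

#' Sankey-style counts of conserved interactions per tissue combination
#'
#' Groups conserved interactions by their exact tissue-combination signature
#' (sorted, comma-joined); group totals partition the interaction count.
#'
#' @param conserved tibble from [conserved_impaired_interactions()].
#' @return tibble (tissue_combination, n_tissues, n_interactions, n_mirnas,
#'   n_genes) plus the single-tissue totals as attribute
#'   `single_tissue_totals`.
#' @export
tissue_interaction_counts <- function(conserved) {
  if (!nrow(conserved)) {
    out <- tibble(tissue_combination = character(), n_tissues = integer(),
                  n_interactions = integer(), n_mirnas = integer(),
                  n_genes = integer())
    attr(out, "single_tissue_totals") <- tibble(tissue = character(),
                                                n_interactions = integer())
    return(out)
  }
  sig <- vapply(strsplit(conserved$tissues, ",", fixed = TRUE),
                function(x) paste(sort(unique(x)), collapse = ","),
                character(1))
  out <- tibble(sig = sig,
                mirna = conserved$mouse_mirna,
                gene = conserved$mouse_gene) |>
    group_by(.data$sig) |>
    summarise(n_interactions = n(),
              n_mirnas = n_distinct(.data$mirna),
              n_genes = n_distinct(.data$gene), .groups = "drop") |>
    mutate(n_tissues = lengths(strsplit(.data$sig, ",", fixed = TRUE))) |>
    rename(tissue_combination = "sig") |>
    select("tissue_combination", "n_tissues", "n_interactions",
           "n_mirnas", "n_genes") |>
    arrange(.data$n_tissues, .data$tissue_combination)
  singles <- tibble(tissue = unlist(strsplit(sig, ",", fixed = TRUE))) |>
    dplyr::count(.data$tissue, name = "n_interactions")
  attr(out, "single_tissue_totals") <- singles
  out
}
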