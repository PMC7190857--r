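# Enrichment statistics: 2x2 contingency tests (chi-square without
# continuity correction, two-sided Fisher, cross-product odds ratio,
# expected cells), hypergeometric set-overlap with representation factor,
# Benjamini-Hochberg correction, the tissue/QTL enrichment suite, and a
# generic over-representation test.
#
# The 2x2 layout is rows = (group1, group2) x cols = (selected, rest). For
# the knockout-phenotype tables this means rows = (other phenotype,
# metabolic phenotype) and cols = (in candidate set, rest), so the odds
# ratio (c*b)/(a*d) places the enriched metabolic/candidate cell in the
# numerator. No Yates correction is applied anywhere: the chi-square is the
# plain sum of (O-E)^2/E on 1 df.

#' Build a 2x2 contingency table with margins
#' @param a,b,c,d non-negative integer cells, rows (group1, group2) x cols
#'   (selected, rest): a = group1/selected, b = group1/rest,
#'   c = group2/selected, d = group2/rest.
#' @return object of class `contingency_2x2`.
#' @export
contingency_2x2 <- function(a, b, c, d) {
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(cells < 0) || any(cells != round(cells))) {
    stop_ctx("contingency cells must be non-negative integers")
  }
  structure(list(a = a, b = b, c = c, d = d,
                 row_totals = c(a + b, c + d),
                 col_totals = c(a + c, b + d),
                 total = a + b + c + d),
            class = "contingency_2x2")
}

as_matrix_2x2 <- function(tab) {
  matrix(c(tab$a, tab$b, tab$c, tab$d), nrow = 2, byrow = TRUE)
}

#' Expected cell counts under independence
#' @param tab a `contingency_2x2`.
#' @return numeric vector (a, b, c, d) of expected values E_ij =
#'   row_i * col_j / total; they conserve the margins.
#' @export
expected_counts <- function(tab) {
  e <- outer(tab$row_totals, tab$col_totals) / tab$total
  c(a = e[1, 1], b = e[1, 2], c = e[2, 1], d = e[2, 2])
}

#' Chi-square test of independence on a 2x2 table (1 df)
#' @param tab a `contingency_2x2`.
#' @param continuity_correction apply the Yates correction (default FALSE).
#' @return list(statistic, p); errors if any expected cell is zero.
#' @export
chi_square_2x2 <- function(tab, continuity_correction = FALSE) {
  if (tab$total <= 0) stop_ctx("empty contingency table")
  if (any(expected_counts(tab) == 0)) {
    stop_ctx("an expected cell is zero; use fisher_exact_2x2() instead")
  }
  res <- suppressWarnings(
    chisq.test(as_matrix_2x2(tab), correct = continuity_correction)
  )
  list(statistic = unname(res$statistic), p = unname(res$p.value))
}

#' Two-sided Fisher exact test on a 2x2 table
#'
#' Point-probability method: the p-value sums the probabilities of all
#' tables with the observed margins whose probability does not exceed that
#' of the observed table.
#' @param tab a `contingency_2x2`.
#' @return two-sided p-value.
#' @export
fisher_exact_2x2 <- function(tab) {
  unname(fisher.test(as_matrix_2x2(tab))$p.value)
}

#' Cross-product odds ratio of a 2x2 table
#'
#' With rows (other, selected-phenotype) x cols (filtered, rest), returns
#' OR = (c*b)/(a*d): the enriched cell (selected phenotype within the
#' filtered set) sits in the numerator, so OR > 1 iff that cell exceeds its
#' expectation.
#' @param tab a `contingency_2x2`.
#' @return list(odds_ratio, infinite = flag for a zero denominator cell).
#' @export
odds_ratio <- function(tab) {
  num <- tab$c * tab$b
  den <- tab$a * tab$d
  if (den == 0) {
    return(list(odds_ratio = if (num == 0) NaN else Inf, infinite = TRUE))
  }
  list(odds_ratio = num / den, infinite = FALSE)
}

#' Full enrichment result for one 2x2 table
#' @param tab a `contingency_2x2`. @param label free-text label.
#' @return one-row tibble: label, cells, statistic, p_chi2, p_fisher,
#'   odds_ratio and the four expected cells.
#' @export
enrichment_2x2 <- function(tab, label = "") {
  e <- expected_counts(tab)
  chi <- chi_square_2x2(tab)
  tibble(label = label, a = tab$a, b = tab$b, c = tab$c, d = tab$d,
         statistic = chi$statistic, p_chi2 = chi$p,
         p_fisher = fisher_exact_2x2(tab),
         odds_ratio = odds_ratio(tab)$odds_ratio,
         exp_a = e[["a"]], exp_b = e[["b"]], exp_c = e[["c"]], exp_d = e[["d"]])
}

#' Hypergeometric overlap of two gene sets
#'
#' Upper-tail probability P(X >= k) for X ~ Hypergeometric(N, nA, nB),
#' with the representation factor k*N/(nA*nB) = observed/expected overlap.
#'
#' @param N universe size. @param nA,nB set sizes. @param k observed overlap.
#' @return tibble: universe_size, set_a, set_b, overlap, expected,
#'   representation_factor, p.
#' @export
hypergeometric_overlap <- function(N, nA, nB, k) {
  stopifnot(k <= min(nA, nB), nA <= N, nB <= N, k >= 0)
  expected <- nA * nB / N
  tibble(universe_size = N, set_a = nA, set_b = nB, overlap = k,
         expected = expected,
         representation_factor = if (expected > 0) k / expected else NaN,
         p = phyper(k - 1, nA, N - nA, nB, lower.tail = FALSE))
}

#' Benjamini-Hochberg adjusted p-values (input order preserved)
#' @param pvalues numeric vector in [0, 1].
#' @return adjusted p-values, monotone step-up, capped at 1.
#' @export
benjamini_hochberg <- function(pvalues) {
  stopifnot(all(pvalues >= 0 & pvalues <= 1, na.rm = TRUE))
  p.adjust(pvalues, method = "BH")
}

#' Tissue-level or per-QTL enrichment of site-SNP genes inside QTL
#'
#' For each tissue (scope "global") or each (tissue, QTL) pair (scope
#' "per-qtl"), builds the 2x2 table rows = (in QTL, not in QTL) x cols =
#' (with site-SNP, without) over that tissue's up-regulated genes, and
#' applies the chi-square (no correction), Fisher and odds-ratio tests.
#' Tables with an empty margin (e.g. a tissue with zero in-QTL genes) are
#' flagged untestable and excluded from the BH family.
#'
#' @param up_sets tibble (tissue, gene_id) from [filter_upregulated()].
#' @param impaired_genes character vector of genes with a site-SNP.
#' @param qtl_assign tibble from [assign_genes_to_qtl()]; genes absent from
#'   it are excluded (no annotation).
#' @param scope "global" or "per-qtl".
#' @return tibble with one row per test: tissue (, qtl_id), cells a..d
#'   (a = inQTL/with-SNP, b = inQTL/without, c = outQTL/with, d =
#'   outQTL/without), statistic, p_chi2, p_fisher, odds_ratio, testable,
#'   p_adj (BH over the testable family).
#' @export
qtl_enrichment_suite <- function(up_sets, impaired_genes, qtl_assign,
                                 scope = c("global", "per-qtl")) {
  scope <- match.arg(scope)
  tissues <- sort(unique(up_sets$tissue))
  qtl_sets <- if (scope == "per-qtl") {
    ids <- sort(unique(unlist(strsplit(qtl_assign$qtl_ids[qtl_assign$in_qtl],
                                       ",", fixed = TRUE))))
    setNames(lapply(ids, function(q) {
      qtl_assign$gene_id[vapply(strsplit(qtl_assign$qtl_ids, ",", fixed = TRUE),
                                function(x) q %in% x, logical(1))]
    }), ids)
  } else {
    list(all = qtl_assign$gene_id[qtl_assign$in_qtl])
  }
  rows <- list()
  for (ti in tissues) {
    genes <- intersect(up_sets$gene_id[up_sets$tissue == ti],
                       qtl_assign$gene_id)
    has_snp <- genes %in% impaired_genes
    for (qi in names(qtl_sets)) {
      in_q <- genes %in% qtl_sets[[qi]]
      a <- sum(in_q & has_snp); b <- sum(in_q & !has_snp)
      cc <- sum(!in_q & has_snp); d <- sum(!in_q & !has_snp)
      tab <- contingency_2x2(a, b, cc, d)
      testable <- all(tab$row_totals > 0) && all(tab$col_totals > 0)
      row <- tibble(tissue = ti, qtl_id = qi, a = a, b = b, c = cc, d = d,
                    n_genes = length(genes), testable = testable)
      if (testable) {
        chi <- chi_square_2x2(tab)
        row$statistic <- chi$statistic
        row$p_chi2 <- chi$p
        row$p_fisher <- fisher_exact_2x2(tab)
        row$odds_ratio <- if (b * cc == 0) Inf else (a * d) / (b * cc)
      } else {
        row$statistic <- NA_real_; row$p_chi2 <- NA_real_
        row$p_fisher <- NA_real_; row$odds_ratio <- NA_real_
      }
      rows[[length(rows) + 1L]] <- row
    }
  }
  out <- bind_rows(rows)
  out$p_adj <- NA_real_
  if (any(out$testable)) {
    out$p_adj[out$testable] <- benjamini_hochberg(out$p_chi2[out$testable])
  }
  if (scope == "global") out$qtl_id <- NULL
  out
}

#' Generic over-representation test (hypergeometric per category)
#'
#' In-package analog of web-service pathway enrichment: each category is
#' tested for over-representation in `gene_set` against a fixed gene
#' universe, with BH correction across categories.
#'
#' @param gene_set character vector of selected genes.
#' @param category_sets named list of character vectors.
#' @param universe character vector defining the background; genes outside
#'   it are ignored on both sides.
#' @param alpha significance threshold on the adjusted p (default 0.05).
#' @return tibble: category, universe_size, set_size, category_size,
#'   overlap, expected, representation_factor, p, p_adj, significant.
#' @export
over_representation <- function(gene_set, category_sets, universe,
                                alpha = 0.05) {
  stopifnot(length(category_sets) >= 1, !is.null(names(category_sets)))
  universe <- unique(universe)
  gs <- intersect(unique(gene_set), universe)
  N <- length(universe)
  rows <- lapply(names(category_sets), function(nm) {
    cat_g <- intersect(unique(category_sets[[nm]]), universe)
    k <- length(intersect(gs, cat_g))
    h <- hypergeometric_overlap(N, length(gs), length(cat_g), k)
    tibble(category = nm, universe_size = N, set_size = length(gs),
           category_size = length(cat_g), overlap = k,
           expected = h$expected,
           representation_factor = h$representation_factor, p = h$p)
  })
  out <- bind_rows(rows)
  out$p_adj <- benjamini_hochberg(out$p)
  out$significant <- out$p_adj < alpha
  out
}
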