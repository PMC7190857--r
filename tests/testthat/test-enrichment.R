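# Contingency statistics, hypergeometric overlap, BH correction.

tab_impc <- contingency_2x2(13, 5102, 8, 1116)
tab_mgi <- contingency_2x2(18, 14461, 7, 1738)

test_that("knockout-phenotype contingency tables reproduce the published stats", {
  expect_equal(round(chi_square_2x2(tab_impc)$p, 3), 0.016)
  expect_equal(round(chi_square_2x2(tab_mgi)$p, 3), 0.005)
  expect_equal(round(odds_ratio(tab_impc)$odds_ratio, 2), 2.81)
  expect_equal(round(odds_ratio(tab_mgi)$odds_ratio, 2), 3.24)
  expect_equal(round(expected_counts(tab_impc)[["a"]]), 17)
  expect_equal(round(expected_counts(tab_mgi)[["a"]]), 22)
})

test_that("a perfectly proportional table gives statistic 0 and p 1", {
  tab <- contingency_2x2(10, 90, 20, 180)
  res <- chi_square_2x2(tab)
  expect_equal(res$statistic, 0)
  expect_equal(res$p, 1)
  expect_equal(fisher_exact_2x2(tab), 1)
  expect_equal(odds_ratio(contingency_2x2(5, 5, 5, 5))$odds_ratio, 1)
})

test_that("expected cells conserve the margins and the grand total", {
  set.seed(9)
  for (rep in 1:10) {
    cells <- sample.int(500, 4)
    tab <- contingency_2x2(cells[1], cells[2], cells[3], cells[4])
    e <- expected_counts(tab)
    expect_equal(sum(e), tab$total)
    expect_equal(e[["a"]] + e[["b"]], tab$row_totals[1])
    expect_equal(e[["a"]] + e[["c"]], tab$col_totals[1])
    # OR > 1 iff the enriched cell exceeds its expectation
    or <- odds_ratio(tab)$odds_ratio
    expect_equal(or > 1, tab$c > e[["c"]])
  }
})

test_that("a zero expected cell directs the user to Fisher", {
  expect_error(chi_square_2x2(contingency_2x2(0, 0, 5, 5)), "fisher")
})

test_that("two-sided Fisher equals enumeration over fixed-margin tables", {
  cases <- list(c(1, 9, 11, 3), c(2, 7, 8, 2), c(5, 1, 0, 6), c(3, 3, 3, 3))
  for (cs in cases) {
    tab <- contingency_2x2(cs[1], cs[2], cs[3], cs[4])
    expect_equal(fisher_exact_2x2(tab),
                 brute_fisher(cs[1], cs[2], cs[3], cs[4]),
                 tolerance = 1e-10, info = paste(cs, collapse = ","))
  }
  # chi-square and Fisher agree in the rejection decision on the IMPC table
  expect_equal(fisher_exact_2x2(tab_impc) < 0.05,
               chi_square_2x2(tab_impc)$p < 0.05)
})

test_that("hypergeometric overlap: representation factor and degenerate cases", {
  h <- hypergeometric_overlap(100, 20, 30, 12)
  expect_equal(h$expected, 6)
  expect_equal(h$representation_factor, 2)
  full <- hypergeometric_overlap(50, 50, 50, 50)
  expect_equal(full$p, 1)
  expect_equal(full$representation_factor, 1)
})

test_that("hypergeometric tail equals direct summation for small universes", {
  set.seed(77)
  for (rep in 1:20) {
    N <- sample(10:60, 1)
    nA <- sample.int(N, 1)
    nB <- sample.int(N, 1)
    lo <- max(0, nA + nB - N)
    k <- sample(lo:min(nA, nB), 1)
    expect_equal(hypergeometric_overlap(N, nA, nB, k)$p,
                 brute_hyper_tail(N, nA, nB, k),
                 tolerance = 1e-12,
                 info = sprintf("N=%d nA=%d nB=%d k=%d", N, nA, nB, k))
  }
})

test_that("BH correction reproduces the published corrected tissue p-values", {
  adj <- benjamini_hochberg(c(0.0016, 0.023, 0.048, 0.197))
  expect_equal(round(adj, 3), c(0.006, 0.046, 0.064, 0.197))
})

test_that("BH preserves order and is a monotone step-up capped at 1", {
  expect_equal(benjamini_hochberg(0.03), 0.03)
  expect_equal(benjamini_hochberg(rep(0.02, 5)), rep(0.02, 5))
  set.seed(8)
  p <- runif(20)
  adj <- benjamini_hochberg(p)
  expect_true(all(diff(adj[order(p)]) >= -1e-12))  # monotone in sorted order
  expect_true(all(adj <= 1 & adj >= p))
})

test_that("the QTL enrichment suite flags degenerate tissues as untestable", {
  up <- tibble::tibble(tissue = c("gWAT", "gWAT", "BAT"),
                       gene_id = c("g1", "g2", "g3"))
  qtl_assign <- tibble::tibble(gene_id = paste0("g", 1:3),
                               qtl_ids = c("q1", "", ""),
                               in_qtl = c(TRUE, FALSE, FALSE))
  res <- qtl_enrichment_suite(up, impaired_genes = "g1", qtl_assign)
  # BAT has a single gene, not in any QTL -> empty row margin -> untestable
  expect_false(res$testable[res$tissue == "BAT"])
  expect_true(is.na(res$p_adj[res$tissue == "BAT"]))
})

test_that("over-representation hits the extremes and the tail-sum oracle", {
  universe <- paste0("g", 1:40)
  gs <- paste0("g", 1:10)
  res <- over_representation(gs, list(self = gs, disjoint = paste0("g", 30:40)),
                             universe)
  expect_lt(res$p[res$category == "self"], 1e-6)
  expect_equal(res$p[res$category == "disjoint"],
               brute_hyper_tail(40, 10, 11, 0))
  disj <- over_representation(gs, list(none = paste0("g", 11:20)), universe)
  expect_equal(disj$p, brute_hyper_tail(40, 10, 10, 0))
})
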