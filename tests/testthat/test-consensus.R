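# Expressed-miRNA filter and consensus voting.

mk_preds <- function(df) {
  out <- tibble::as_tibble(df)
  attr(out, "roster") <- c("A", "B", "C", "D", "E")
  out
}

test_that("expression filter is strictly greater-than the read-count threshold", {
  m <- tibble::tibble(accession = c("m1", "m2", "m3"),
                      read_count = c(6L, 5L, 0L))
  expect_equal(filter_expressed_mirnas(m), "m1")
  expect_equal(filter_expressed_mirnas(m[0, ]), character(0))
})

test_that("3-of-5 voting keeps supported pairs and takes sites from the site tool", {
  preds <- mk_preds(data.frame(
    tool = c("A", "B", "C", "A", "B", "B", "C", "D"),
    mirna = c("m1", "m1", "m1", "m2", "m2", "m3", "m3", "m3"),
    transcript_id = "t1",
    utr_start = c(10L, 12L, 10L, 50L, 50L, 5L, 5L, 5L),
    utr_end = c(31L, 30L, 31L, 71L, 71L, 26L, 26L, 26L),
    score = 1))
  cons <- consensus_vote(preds, expressed = c("m1", "m2", "m3"),
                         min_support = 3, site_tool = "A")
  # m1: 3 tools incl. site tool -> kept, support 3
  expect_equal(cons$pairs$support[cons$pairs$mirna == "m1"], 3L)
  # m2: 2 tools -> dropped
  expect_false("m2" %in% cons$pairs$mirna)
  # m3: 3 tools but no site-tool site -> dropped, counted
  expect_false("m3" %in% cons$pairs$mirna)
  expect_equal(cons$dropped_no_site, 1L)
  # overlapping site-tool intervals are merged by union
  m1_sites <- cons$sites[cons$sites$mirna == "m1", ]
  expect_equal(nrow(m1_sites), 1)
  expect_equal(m1_sites$utr_start, 10L)
  expect_equal(m1_sites$utr_end, 31L)
})

test_that("unexpressed miRNAs never enter the vote", {
  preds <- mk_preds(data.frame(tool = c("A", "B", "C"), mirna = "m1",
                               transcript_id = "t1", utr_start = 0L,
                               utr_end = 21L, score = 1))
  cons <- consensus_vote(preds, expressed = character(0), site_tool = "A")
  expect_equal(nrow(cons$pairs), 0)
})

test_that("min_support above the roster size is an error", {
  preds <- mk_preds(data.frame(tool = "A", mirna = "m1",
                               transcript_id = "t1", utr_start = 0L,
                               utr_end = 21L, score = 1))
  expect_error(consensus_vote(preds, "m1", min_support = 6, site_tool = "A"),
               "roster")
  expect_error(consensus_vote(preds, "m1", site_tool = "nosuch"), "roster")
})

test_that("vote support matches a brute-force double-loop recount", {
  set.seed(101)
  for (rep in 1:5) {
    preds <- mk_preds(data.frame(
      tool = sample(c("A", "B", "C", "D", "E"), 200, replace = TRUE),
      mirna = sample(paste0("m", 1:8), 200, replace = TRUE),
      transcript_id = sample(paste0("t", 1:6), 200, replace = TRUE),
      utr_start = 0L, utr_end = 21L, score = 1))
    oracle <- brute_support(as.data.frame(preds))
    oracle <- oracle[oracle$support >= 3, ]
    cons <- consensus_vote(preds, expressed = paste0("m", 1:8),
                           min_support = 3, site_tool = "A")
    # pairs additionally require a site-tool record
    has_a <- unique(paste(preds$mirna, preds$transcript_id)[preds$tool == "A"])
    oracle <- oracle[paste(oracle$mirna, oracle$transcript_id) %in% has_a, ]
    expect_setequal(paste(cons$pairs$mirna, cons$pairs$transcript_id,
                          cons$pairs$support),
                    paste(oracle$mirna, oracle$transcript_id, oracle$support))
  }
})

test_that("vote is monotone in min_support", {
  b <- small_bundle()
  expressed <- filter_expressed_mirnas(b$mirnas)
  keys <- lapply(2:5, function(ms) {
    cons <- consensus_vote(b$predictions, expressed, min_support = ms)
    paste(cons$pairs$mirna, cons$pairs$transcript_id)
  })
  for (i in 2:4) expect_true(all(keys[[i]] %in% keys[[i - 1]]))
  # support of every output respects the threshold
  cons <- consensus_vote(b$predictions, expressed, min_support = 3)
  expect_true(all(cons$pairs$support >= 3))
})

test_that("validation flags mark exactly the listed (miRNA, gene) pairs", {
  preds <- mk_preds(data.frame(tool = c("A", "B", "C"), mirna = "m1",
                               transcript_id = "tA", utr_start = 0L,
                               utr_end = 21L, score = 1))
  cons <- consensus_vote(preds, "m1", site_tool = "A")
  tx <- toy_transcripts()
  flagged <- attach_validation(cons, tibble::tibble(mirna = "m1",
                                                    gene_id = "gA"), tx)
  expect_true(flagged$pairs$validated)
  unflagged <- attach_validation(cons, tibble::tibble(mirna = character(),
                                                      gene_id = character()),
                                 tx)
  expect_false(unflagged$pairs$validated)
})
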