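# UTR-to-genome projection and variant/site intersection.

test_that("plus-strand projection is offset addition", {
  tx <- toy_transcripts()[1, ]
  blk <- project_utr_to_genomic(tx, 10L, 17L)
  expect_equal(blk$start, 1010L)
  expect_equal(blk$end, 1017L)
})

test_that("minus-strand projection maps transcript-ascending to genome-descending", {
  tx <- toy_transcripts()[2, ]
  blk <- project_utr_to_genomic(tx, 10L, 17L)
  expect_equal(blk$start, 1183L)
  expect_equal(blk$end, 1190L)
  # per-base oracle: projecting each base singly and uniting gives the block
  singles <- vapply(10:16, function(u) {
    project_utr_to_genomic(tx, u, u + 1L)$start
  }, integer(1))
  expect_setequal(singles, 1183:1189)
})

test_that("a site spanning a UTR intron projects to blocks summing to its length", {
  tx <- toy_transcripts()[3, ]  # blocks (60,64) + (80,90)
  blk <- project_utr_to_genomic(tx, 2L, 9L)
  expect_equal(nrow(blk), 2)
  expect_equal(sum(blk$end - blk$start), 7)
  expect_equal(blk$start, c(62L, 80L))
  expect_equal(blk$end, c(64L, 85L))
  # per-base bijection: single-base projections concatenate to the blocks
  singles <- lapply(2:8, function(u) project_utr_to_genomic(tx, u, u + 1L))
  pos <- vapply(singles, function(s) s$start, integer(1))
  expect_setequal(pos, c(62L, 63L, 80L:84L))
})

test_that("intervals beyond the UTR length are rejected", {
  tx <- toy_transcripts()[3, ]  # total UTR length 14
  expect_error(project_utr_to_genomic(tx, 10L, 15L), "exceeds")
})

mk_cons <- function(sites) structure(list(sites = sites), class = "consensus_interactions")

test_that("containment is half-open: a variant at the site end is no hit", {
  tx <- toy_transcripts()[1, ]
  sites <- tibble::tibble(mirna = "m1", transcript_id = "tA",
                          utr_start = 10L, utr_end = 17L)
  vars <- tibble::tibble(chrom = "chr1", pos0 = c(1012L, 1017L),
                         id = c("v1", "v2"),
                         ref = c("A", "A"), alt = c("G", "G"))
  hits <- intersect_variants_with_sites(vars, mk_cons(sites), tx)
  expect_equal(hits$id, "v1")
  expect_equal(hits$offset_in_site, 2L)
})

test_that("offsets run in transcript orientation on the minus strand", {
  tx <- toy_transcripts()[2, ]
  sites <- tibble::tibble(mirna = "m1", transcript_id = "tB",
                          utr_start = 10L, utr_end = 17L)
  # genomic block is [1183,1190); genomic 1189 is transcript-first base
  vars <- tibble::tibble(chrom = "chr1", pos0 = c(1189L, 1183L),
                         id = c("v5p", "v3p"), ref = "A", alt = "G")
  hits <- intersect_variants_with_sites(vars, mk_cons(sites), tx)
  expect_equal(hits$offset_in_site[hits$id == "v5p"], 0L)
  expect_equal(hits$offset_in_site[hits$id == "v3p"], 6L)
})

test_that("interval-index intersection equals nested-loop brute force", {
  tx <- toy_transcripts()
  set.seed(202)
  for (rep in 1:6) {
    n_sites <- 30
    which_tx <- sample(1:3, n_sites, replace = TRUE)
    max_len <- c(200L, 200L, 14L)
    s0 <- vapply(which_tx, function(i) sample.int(max_len[i] - 5L, 1) - 1L,
                 integer(1))
    len <- vapply(seq_len(n_sites), function(i)
      sample.int(min(5L, max_len[which_tx[i]] - s0[i]), 1), integer(1))
    sites <- tibble::tibble(
      mirna = paste0("m", sample(1:4, n_sites, replace = TRUE)),
      transcript_id = tx$transcript_id[which_tx],
      utr_start = s0, utr_end = s0 + len) |> dplyr::distinct()
    vars <- tibble::tibble(
      chrom = sample(c("chr1", "chr2"), 300, replace = TRUE),
      pos0 = sample(0:1300, 300),
      id = paste0("v", 1:300), ref = "A", alt = "G")
    hits <- intersect_variants_with_sites(vars, mk_cons(sites), tx)
    # oracle: project each site independently, then test every pair
    proj <- list()
    for (k in seq_len(nrow(sites))) {
      t1 <- tx[tx$transcript_id == sites$transcript_id[k], ]
      blk <- project_utr_to_genomic(t1, sites$utr_start[k], sites$utr_end[k])
      proj[[k]] <- cbind(rep(k, nrow(blk)), blk$start, blk$end)
    }
    proj <- do.call(rbind, proj)
    blk_chrom <- sites$transcript_id[proj[, 1]]
    blk_chrom <- tx$chrom[match(blk_chrom, tx$transcript_id)]
    bh <- brute_hits(vars$chrom, vars$pos0, blk_chrom, proj[, 2], proj[, 3])
    want <- sort(paste(vars$id[bh[, 1]],
                       sites$mirna[proj[bh[, 2], 1]],
                       sites$transcript_id[proj[bh[, 2], 1]],
                       sites$utr_start[proj[bh[, 2], 1]]))
    got <- sort(paste(hits$id, hits$mirna, hits$transcript_id,
                      hits$site_utr_start))
    expect_equal(got, want, info = paste("rep", rep))
  }
})

test_that("offset invariant holds on the synthetic bundle", {
  b <- small_bundle()
  expressed <- filter_expressed_mirnas(b$mirnas)
  cons <- consensus_vote(b$predictions, expressed)
  hits <- intersect_variants_with_sites(b$variants, cons, b$transcripts)
  expect_true(nrow(hits) > 0)
  len <- hits$site_utr_end - hits$site_utr_start
  expect_true(all(hits$offset_in_site >= 0 & hits$offset_in_site < len))
})

test_that("the SNP-frequency window count is a closed symmetric flank", {
  vars <- tibble::tibble(chrom = "chr1", pos0 = c(100L, 60000L))
  pos <- tibble::tibble(chrom = "chr1", position = 100L)
  expect_equal(snp_frequency_track(vars, pos, flank = 50000L)$count, 1L)
  expect_equal(snp_frequency_track(vars, pos, flank = 59900L)$count, 2L)
  # degenerate flank counts only exact positions
  expect_equal(snp_frequency_track(vars, pos, flank = 0L)$count, 1L)
  none <- tibble::tibble(chrom = "chr9", position = 100L)
  expect_equal(snp_frequency_track(vars, none, flank = 50000L)$count, 0L)
})

test_that("window counts equal the naive count on random instances", {
  set.seed(303)
  vars <- tibble::tibble(chrom = sample(c("chr1", "chr2"), 500, replace = TRUE),
                         pos0 = sample.int(1e6, 500))
  qry <- tibble::tibble(chrom = sample(c("chr1", "chr2"), 40, replace = TRUE),
                        position = sample.int(1e6, 40))
  got <- snp_frequency_track(vars, qry, flank = 25000L)
  for (i in seq_len(nrow(qry))) {
    expect_equal(got$count[i],
                 brute_window_count(vars$chrom, vars$pos0,
                                    qry$chrom[i], qry$position[i], 25000L))
  }
})

test_that("impaired-gene extraction is the distinct gene set", {
  hits <- tibble::tibble(gene_id = c("g2", "g1", "g2"))
  expect_equal(genes_with_impaired_sites(hits), c("g1", "g2"))
  expect_equal(genes_with_impaired_sites(hits[0, ]), character(0))
})
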