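# Local alignment, seed conservation, cross-species interaction mapping.

test_that("self-alignment of a 22-mer scores its full length", {
  s <- paste(sample(c("A", "C", "G", "U"), 22, replace = TRUE), collapse = "")
  al <- local_align(s, s)
  expect_equal(al$score, 22)
  expect_equal(al$identity, 1.0)
  expect_equal(al$a_start, 1L)
  expect_equal(al$a_end, 22L)
})

test_that("sequences with no common 2-mer score at most one match", {
  al <- local_align("AAAAAAAAAA", "CCCCCCCCCC")
  expect_equal(al$score, 0)
  al2 <- local_align("AAAAAAAAAA", "CCCCACCCCC")
  expect_equal(al2$score, 1)
  expect_error(local_align("", "ACGU"), "empty")
})

test_that("alignment scores equal exhaustive search over all local alignments", {
  set.seed(606)
  for (rep in 1:12) {
    a <- paste(sample(c("A", "C", "G", "U"), sample(4:7, 1), replace = TRUE),
               collapse = "")
    b <- paste(sample(c("A", "C", "G", "U"), sample(4:7, 1), replace = TRUE),
               collapse = "")
    expect_equal(local_align(a, b)$score, brute_local_score(a, b),
                 info = paste(a, b))
  }
})

test_that("alignment scores agree with an independent aligner on 20-mers", {
  set.seed(607)
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                  baseOnly = TRUE)
  for (rep in 1:25) {
    a <- paste(sample(c("A", "C", "G", "U"), 20, replace = TRUE), collapse = "")
    b <- paste(sample(c("A", "C", "G", "U"), 20, replace = TRUE), collapse = "")
    ref <- Biostrings::pairwiseAlignment(
      chartr("U", "T", a), chartr("U", "T", b), type = "local",
      substitutionMatrix = mat, gapOpening = 0, gapExtension = 2,
      scoreOnly = TRUE)
    expect_equal(local_align(a, b)$score, ref, info = paste(a, b))
  }
})

test_that("alignment score is symmetric and bounded by the shorter sequence", {
  set.seed(608)
  for (rep in 1:10) {
    a <- paste(sample(c("A", "C", "G", "U"), 15, replace = TRUE), collapse = "")
    b <- paste(sample(c("A", "C", "G", "U"), 22, replace = TRUE), collapse = "")
    sa <- local_align(a, b)$score
    expect_equal(sa, local_align(b, a)$score)
    expect_lte(sa, 15)
  }
})

test_that("seed conservation is exactly positions 2-8", {
  s <- "ACGUACGUACGUACGUACGUAC"
  expect_true(seed_conserved(s, s))
  expect_true(seed_conserved(s, chartr("U", "T", s)))  # U/T normalisation
  flip <- function(x, i) {
    ch <- strsplit(x, "")[[1]]
    ch[i] <- setdiff(c("A", "C", "G", "U"), ch[i])[1]
    paste(ch, collapse = "")
  }
  for (i in 2:8) expect_false(seed_conserved(s, flip(s, i)), info = i)
  for (i in c(1, 9:22)) expect_true(seed_conserved(s, flip(s, i)), info = i)
  expect_error(seed_conserved("ACGUACG", s), "8 nt")
})

mk_mirnas <- function(seqs, prefix) {
  tibble::tibble(accession = paste0(prefix, seq_along(seqs)),
                 name = paste0(prefix, "-name-", seq_along(seqs)),
                 mature_seq = seqs)
}

test_that("a mirrored human set matches itself; scrambled seeds match nothing", {
  set.seed(609)
  seqs <- vapply(1:6, function(i)
    paste(sample(c("A", "C", "G", "U"), 22, replace = TRUE), collapse = ""),
    character(1))
  mouse <- mk_mirnas(seqs, "mmu")
  human <- mk_mirnas(seqs, "hsa")
  m <- match_mirnas_cross_species(mouse, human)
  self <- m[m$mouse_acc == paste0("mmu", 1:6) &
              m$human_acc == paste0("hsa", 1:6), ]
  expect_equal(nrow(self), 6)
  # scramble each seed (reverse positions 2-8) -> no accepted pairs
  scram <- vapply(seqs, function(s) {
    ch <- strsplit(s, "")[[1]]
    ch[2:8] <- c(ch[8:3], setdiff(c("A","C","G","U"), ch[2])[1])
    paste(ch, collapse = "")
  }, character(1))
  scram_ok <- vapply(seq_along(seqs), function(i)
    substr(scram[i], 2, 8) != substr(seqs[i], 2, 8), logical(1))
  human2 <- mk_mirnas(scram[scram_ok], "hsa")
  m2 <- match_mirnas_cross_species(mouse[scram_ok, ], human2)
  m2 <- m2[match(m2$mouse_acc, mouse$accession[scram_ok]) ==
             match(m2$human_acc, human2$accession), ]
  expect_equal(nrow(m2), 0)
})

test_that("the planted seed-conserved fraction is recovered", {
  b <- small_bundle()
  m <- match_mirnas_cross_species(b$mirnas, b$human_mirnas)
  planted <- b$truth$conserved_mirnas
  key <- paste(m$mouse_acc, m$human_acc)
  expect_true(all(paste(planted$mouse_acc, planted$human_acc) %in% key))
})

test_that("conserved interactions obey the conjunctive rule", {
  hits <- tibble::tibble(mirna = "M1", gene_id = "g1", tissues = "gWAT")
  orth <- tibble::tibble(mouse_gene = "g1", human_gene = "h_g1")
  aln <- tibble::tibble(mouse_acc = "M1", human_name = "hsa-miR-1")
  snp <- tibble::tibble(variant_id = "rs1", human_gene = "h_g1",
                        human_mirna = "hsa-miR-1", effect_class = "break")
  full <- conserved_impaired_interactions(hits, orth, aln, snp)
  expect_equal(nrow(full), 1)
  expect_equal(full$variant_id, "rs1")
  expect_equal(full$tissues, "gWAT")
  # remove any one leg and the record disappears
  expect_equal(nrow(conserved_impaired_interactions(hits, orth[0, ], aln, snp)), 0)
  expect_equal(nrow(conserved_impaired_interactions(hits, orth, aln[0, ], snp)), 0)
  expect_equal(nrow(conserved_impaired_interactions(hits, orth, aln, snp[0, ])), 0)
})

test_that("enlarging the ortholog map or MirSNP table never removes records", {
  b <- small_bundle()
  res <- analyze_bundle(b, through = "conservation")
  key0 <- paste(res$conserved$mouse_mirna, res$conserved$mouse_gene,
                res$conserved$variant_id)
  bigger <- b
  bigger$orthologs <- dplyr::bind_rows(
    b$orthologs, tibble::tibble(mouse_gene = "zzz", human_gene = "h_zzz"))
  bigger$mirsnp <- dplyr::bind_rows(
    b$mirsnp, tibble::tibble(variant_id = "rs_extra", human_gene = "h_zzz",
                             human_mirna = "none", effect_class = "break"))
  res2 <- analyze_bundle(bigger, through = "conservation")
  key2 <- paste(res2$conserved$mouse_mirna, res2$conserved$mouse_gene,
                res2$conserved$variant_id)
  expect_true(all(key0 %in% key2))
})

test_that("tissue-combination counts partition the conserved interactions", {
  cons <- tibble::tibble(
    mouse_mirna = c("M1", "M2", "M3", "M4"),
    mouse_gene = c("g1", "g2", "g3", "g3"),
    tissues = c("gWAT", "gWAT", "BAT,gWAT,liver,muscle", "gWAT"))
  tc <- tissue_interaction_counts(cons)
  expect_equal(sum(tc$n_interactions), 4)
  expect_equal(tc$n_interactions[tc$tissue_combination == "gWAT"], 3L)
  expect_equal(tc$n_tissues[tc$tissue_combination ==
                              "BAT,gWAT,liver,muscle"], 4L)
  empty <- tissue_interaction_counts(cons[0, ])
  expect_equal(nrow(empty), 0)
})
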