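# Generator contracts: determinism, manifest consistency, seed scanning.

test_that("the same (config, seed) yields byte-identical bundles", {
  cfg <- small_config()
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_bundle(generate_bundle(cfg, seed = 5), d1)
  write_bundle(generate_bundle(cfg, seed = 5), d2)
  files <- sort(list.files(d1))
  expect_equal(files, sort(list.files(d2)))
  for (f in files) {
    expect_identical(readBin(file.path(d1, f), "raw", 2e6),
                     readBin(file.path(d2, f), "raw", 2e6), info = f)
  }
  # a different seed changes the content
  d3 <- withr::local_tempdir()
  write_bundle(generate_bundle(cfg, seed = 6), d3)
  expect_false(identical(readBin(file.path(d1, "variants.vcf"), "raw", 2e6),
                         readBin(file.path(d3, "variants.vcf"), "raw", 2e6)))
})

test_that("perfect tools make the consensus recover exactly the planted sites", {
  cfg <- small_config(
    p_tool = stats::setNames(rep(1, 5),
                             c("miranda", "targetscan", "pita", "rnahybrid",
                               "mirdb")),
    f_tool = stats::setNames(rep(0, 5),
                             c("miranda", "targetscan", "pita", "rnahybrid",
                               "mirdb")))
  b <- generate_bundle(cfg, seed = 9)
  expressed <- filter_expressed_mirnas(b$mirnas)
  cons <- consensus_vote(b$predictions, expressed)
  truth_pairs <- unique(paste(b$truth$true_sites$mirna,
                              b$truth$true_sites$transcript_id))
  truth_pairs <- truth_pairs[sub(" .*", "", truth_pairs) %in% expressed]
  expect_setequal(paste(cons$pairs$mirna, cons$pairs$transcript_id),
                  truth_pairs)
  expect_equal(cons$dropped_no_site, 0L)
  # every manifest site appears verbatim in the site tool's table
  site_tool_tab <- b$predictions[b$predictions$tool == "miranda", ]
  key_sites <- paste(site_tool_tab$mirna, site_tool_tab$transcript_id,
                     site_tool_tab$utr_start, site_tool_tab$utr_end)
  expect_true(all(paste(b$truth$true_sites$mirna,
                        b$truth$true_sites$transcript_id,
                        b$truth$true_sites$utr_start,
                        b$truth$true_sites$utr_end) %in% key_sites))
})

test_that("planted sites carry the exact seed complement in the UTR sequence", {
  b <- small_bundle()
  ts <- b$truth$true_sites
  for (k in sample.int(nrow(ts), 25)) {
    mseq <- b$mirnas$mature_seq[b$mirnas$accession == ts$mirna[k]]
    found <- scan_seed_sites(b$utr_seqs[[ts$transcript_id[k]]], mseq)
    expect_true(ts$seed_utr_start[k] %in% found$utr_start,
                info = paste("site", k))
  }
})

test_that("seed scanning equals brute-force substring search", {
  set.seed(909)
  for (rep in 1:10) {
    utr <- paste(sample(c("A", "C", "G", "U"), 300, replace = TRUE),
                 collapse = "")
    mir <- paste(sample(c("A", "C", "G", "U"), 22, replace = TRUE),
                 collapse = "")
    got <- scan_seed_sites(utr, mir)
    # oracle: slide a window and compare strings
    seed <- substr(mir, 2, 8)
    comp <- c(A = "U", C = "G", G = "C", U = "A")
    pat <- paste(rev(comp[strsplit(seed, "")[[1]]]), collapse = "")
    want <- integer(0)
    for (i in 1:(300 - 6)) {
      if (substr(utr, i, i + 6) == pat) want <- c(want, i - 1L)
    }
    expect_equal(got$utr_start, want)
    expect_equal(got$utr_end, want + 7L)
  }
  none <- scan_seed_sites("AAAAAAAAAA", "AAAAAAAAAAAAAAAAAAAAAA")
  expect_equal(nrow(none), 0)  # seed complement UUUUUUU absent
})

test_that("every manifest entry corresponds to emitted records", {
  b <- small_bundle()
  # disrupted sites point at real variants and real sites
  expect_true(all(b$truth$disrupted$variant_id %in% b$variants$id))
  key_sites <- paste(b$truth$true_sites$mirna, b$truth$true_sites$transcript_id,
                     b$truth$true_sites$utr_start)
  expect_true(all(paste(b$truth$disrupted$mirna,
                        b$truth$disrupted$transcript_id,
                        b$truth$disrupted$utr_start) %in% key_sites))
  # conserved-impaired rows reference emitted MirSNP records and orthologs
  ci <- b$truth$conserved_impaired
  expect_true(all(ci$variant_id %in% b$mirsnp$variant_id))
  expect_true(all(ci$human_gene %in% b$orthologs$human_gene))
  expect_true(all(ci$human_mirna %in% b$human_mirnas$name))
  # upregulated manifest genes pass the DE filter on the emitted table
  up <- filter_upregulated(b$expression)
  expect_setequal(paste(b$truth$upregulated$tissue,
                        b$truth$upregulated$gene_id),
                  paste(up$tissue, up$gene_id))
})

test_that("variants inside QTL are denser than background", {
  b <- small_bundle()
  sig <- significant_qtl(b$qtls)
  qtl_len <- sum(sig$end - sig$start)
  total_len <- sum(b$chrom_lengths)
  gr_v <- b$variants
  in_q <- rep(FALSE, nrow(gr_v))
  for (i in seq_len(nrow(sig))) {
    in_q <- in_q | (gr_v$chrom == sig$chrom[i] & gr_v$pos0 >= sig$start[i] &
                      gr_v$pos0 < sig$end[i])
  }
  dens_in <- sum(in_q) / qtl_len
  dens_out <- sum(!in_q) / (total_len - qtl_len)
  expect_gt(dens_in / dens_out, 1.5)  # planted multiplier is 2.5
})

test_that("infeasible configurations are rejected", {
  expect_error(synth_config(qtl_width = 6e6), "fit")
  expect_error(synth_config(p_upregulated_given_hit = 1.4), "probabilities")
  expect_error(synth_config(qtl_snp_multiplier = 0.5), "multiplier")
})
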