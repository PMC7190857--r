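#!/usr/bin/env Rscript
# Enrichment statistics: hypergeometric overlap of up-regulated and
# impaired-site genes, and the per-tissue / per-QTL chi-square suite with
# BH correction.

suppressPackageStartupMessages(library(mirsitevar))

bundle <- read_bundle("results/bundle")
res <- analyze_bundle(bundle, through = "enrichment")

write_tsv_file(res$enrichment_global, "results/enrichment_global.tsv")
write_tsv_file(res$enrichment_per_qtl, "results/enrichment_per_qtl.tsv")
write_tsv_file(res$overlap_test, "results/overlap_test.tsv")

ot <- res$overlap_test
cat(sprintf("Up-regulated x impaired-site overlap: %d genes, expected %.1f, representation factor %.2f, p = %.3g\n",
            ot$overlap, ot$expected, ot$representation_factor, ot$p))
cat("Tissue-level QTL enrichment (chi-square, BH-corrected):\n")
print(as.data.frame(res$enrichment_global[, c("tissue", "a", "b", "c", "d",
                                              "p_chi2", "odds_ratio",
                                              "p_adj")]))
sig <- res$enrichment_per_qtl[!is.na(res$enrichment_per_qtl$p_adj) &
                                res$enrichment_per_qtl$p_adj < 0.05, ]
cat(nrow(sig), "per-QTL tests significant after BH\n")
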