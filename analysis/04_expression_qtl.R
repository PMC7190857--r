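#!/usr/bin/env Rscript
# Tissue-wise up-regulated gene sets, intersection with impaired-site
# genes, QTL assignment and Venn-style overlap counts.

suppressPackageStartupMessages(library(mirsitevar))

bundle <- read_bundle("results/bundle")
res <- analyze_bundle(bundle, through = "enrichment")

write_tsv_file(res$up_sets, "results/upregulated.tsv")
write_tsv_file(res$qtl_assign, "results/gene_qtl.tsv")
write_tsv_file(res$venn_counts, "results/venn_counts.tsv")

per_tissue <- table(res$up_sets$tissue)
cat("Up-regulated genes per tissue:\n")
print(per_tissue)
cat(length(unique(res$candidates$gene_id)),
    "candidate genes (up-regulated with a site-SNP);",
    length(unique(res$candidates_in_qtl$gene_id)), "of them in QTL\n")
cat("Venn regions over in-QTL candidates:\n")
print(as.data.frame(res$venn_counts[res$venn_counts$count > 0, ]))
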