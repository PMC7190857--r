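#!/usr/bin/env Rscript
# Phenotype annotation of the conserved candidates, knockout-phenotype
# enrichment tables, evidence Venn counts, and the miRNA-gene-phenotype
# regulatory networks.

suppressPackageStartupMessages(library(mirsitevar))

bundle <- read_bundle("results/bundle")
res <- analyze_bundle(bundle, through = "annotation")

write_tsv_file(res$evidence, "results/evidence.tsv")
write_tsv_file(res$phenotype_tests, "results/contingency_tables.tsv")
write_tsv_file(res$evidence_venn, "results/evidence_venn.tsv")
write_tsv_file(res$network$nodes, "results/network_nodes.tsv")
write_tsv_file(res$network$edges, "results/network_edges.tsv")
write_tsv_file(res$network$components, "results/components.tsv")

cat("Knockout-phenotype enrichment of the conserved candidates:\n")
print(as.data.frame(res$phenotype_tests[, c("label", "a", "b", "c", "d",
                                            "p_chi2", "odds_ratio")]))
cat("Network:", nrow(res$network$nodes), "nodes,",
    nrow(res$network$edges), "edges,",
    nrow(res$network$components), "connected components\n")
cat("Largest component:", res$network$components$n_nodes[1], "nodes\n")
cat("\nFunnel counts for this bundle:\n")
print(res$funnel)
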