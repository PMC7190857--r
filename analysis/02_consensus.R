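#!/usr/bin/env Rscript
# Expressed-miRNA filter and 3-of-5 consensus target vote over the per-tool
# prediction tables; sites come from the miRanda-analog site tool.

suppressPackageStartupMessages(library(mirsitevar))

bundle <- read_bundle("results/bundle")
expressed <- filter_expressed_mirnas(bundle$mirnas, min_readcount = 5)
cons <- consensus_vote(bundle$predictions, expressed,
                       min_support = 3, site_tool = "miranda")
cons <- attach_validation(cons, bundle$validated_pairs, bundle$transcripts)

write_tsv_file(cons$pairs, "results/consensus_interactions.tsv")
write_tsv_file(cons$sites, "results/consensus_sites.tsv")

cat(length(expressed), "of", nrow(bundle$mirnas),
    "miRNAs pass the expression filter\n")
cat(nrow(cons$pairs), "consensus interactions (",
    nrow(cons$sites), "merged sites );",
    cons$dropped_no_site, "pairs dropped without a site-tool site\n")
cat(sum(cons$pairs$validated), "interactions carry experimental validation\n")
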