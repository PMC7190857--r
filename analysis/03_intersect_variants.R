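#!/usr/bin/env Rscript
# Project consensus sites to genomic coordinates, intersect with strain
# variants, and compute the 50-kb SNP-frequency track.

suppressPackageStartupMessages(library(mirsitevar))

bundle <- read_bundle("results/bundle")
expressed <- filter_expressed_mirnas(bundle$mirnas)
cons <- consensus_vote(bundle$predictions, expressed)

hits <- intersect_variants_with_sites(bundle$variants, cons,
                                      bundle$transcripts)
track <- snp_frequency_track(bundle$variants, flank = 50000L,
                             chrom_lengths = bundle$chrom_lengths)

write_tsv_file(hits, "results/site_variant_hits.tsv")
write_tsv_file(track, "results/snp_frequency.tsv")

cat(nrow(hits), "variant-in-site hits over",
    length(unique(hits$id)), "distinct variants and",
    length(genes_with_impaired_sites(hits)), "genes\n")
cat(sum(hits$in_seed_region), "hits fall in the seed-pairing region\n")
cat("SNP-frequency track:", nrow(track), "bins; max count",
    max(track$count), "\n")
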