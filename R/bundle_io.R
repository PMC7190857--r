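# Serialisation of a synthetic bundle to the external formats the pipeline
# consumes (GFF3, VCF, FASTA, TSV) and re-loading through the io_formats
# readers. Writing is deterministic: no timestamps, fixed record order, so
# the same bundle always produces byte-identical files.

#' Write a bundle to disk as GFF3 + VCF + FASTA + TSV files
#'
#' @param bundle a `mirsitevar_bundle` from [generate_bundle()].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly. Files: utr.gff3, genes.tsv, variants.vcf,
#'   mirnas.fa, mirna_counts.tsv, human_mirnas.fa, pred_<tool>.tsv,
#'   expression.tsv, qtl.tsv, orthologs.tsv, mirsnp.tsv, phenotypes.tsv,
#'   validated.tsv, utr_sequences.tsv, chromosomes.tsv and the truth
#'   manifest (truth_manifest.tsv + truth_*.tsv).
#' @export
write_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "mirsitevar_bundle"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)

  write_utr_gff3(bundle$transcripts, p("utr.gff3"))
  write_tsv_file(bundle$gene_bodies, p("genes.tsv"))
  write_vcf(bundle$variants, bundle$chrom_lengths, p("variants.vcf"))
  write_mirna_fasta(bundle$mirnas, p("mirnas.fa"))
  write_tsv_file(bundle$mirnas[, c("accession", "read_count")],
                 p("mirna_counts.tsv"))
  write_mirna_fasta(bundle$human_mirnas, p("human_mirnas.fa"))
  for (tool in unique(bundle$predictions$tool)) {
    tab <- bundle$predictions[bundle$predictions$tool == tool,
                              c("mirna", "transcript_id", "utr_start",
                                "utr_end", "score")]
    write_tsv_file(tab, p(paste0("pred_", tool, ".tsv")))
  }
  write_tsv_file(bundle$expression, p("expression.tsv"))
  write_tsv_file(bundle$qtls, p("qtl.tsv"))
  write_tsv_file(bundle$orthologs, p("orthologs.tsv"))
  write_tsv_file(bundle$mirsnp, p("mirsnp.tsv"))
  write_tsv_file(bundle$phenotypes, p("phenotypes.tsv"))
  write_tsv_file(bundle$validated_pairs, p("validated.tsv"))
  write_tsv_file(tibble(transcript_id = names(bundle$utr_seqs),
                        sequence = unname(bundle$utr_seqs)),
                 p("utr_sequences.tsv"))
  write_tsv_file(tibble(chrom = names(bundle$chrom_lengths),
                        length = unname(bundle$chrom_lengths)),
                 p("chromosomes.tsv"))
  write_tsv_file(bundle$truth$conserved_impaired, p("truth_manifest.tsv"))
  write_tsv_file(bundle$truth$true_sites, p("truth_sites.tsv"))
  write_tsv_file(bundle$truth$disrupted, p("truth_disrupted.tsv"))
  write_tsv_file(bundle$truth$conserved_mirnas, p("truth_conserved_mirnas.tsv"))
  write_tsv_file(bundle$truth$upregulated, p("truth_upregulated.tsv"))
  invisible(dir)
}

write_utr_gff3 <- function(transcripts, path) {
  lines <- "##gff-version 3"
  for (i in seq_len(nrow(transcripts))) {
    b <- transcripts$blocks[[i]]
    # emit in genomic order regardless of transcript orientation
    ord <- order(b$start)
    lines <- c(lines,
      sprintf("%s\tmirsitevar\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;gene_id=%s",
              transcripts$chrom[i], min(b$start) + 1L, max(b$end),
              transcripts$strand[i], transcripts$transcript_id[i],
              transcripts$gene_id[i]),
      sprintf("%s\tmirsitevar\tthree_prime_UTR\t%d\t%d\t.\t%s\t.\tID=%s.utr%d;Parent=%s;gene_id=%s",
              transcripts$chrom[i], b$start[ord] + 1L, b$end[ord],
              transcripts$strand[i], transcripts$transcript_id[i],
              seq_along(ord), transcripts$transcript_id[i],
              transcripts$gene_id[i]))
  }
  writeLines(lines, path)
}

write_vcf <- function(variants, chrom_lengths, path) {
  hdr <- c("##fileformat=VCFv4.2",
           sprintf("##contig=<ID=%s,length=%d>", names(chrom_lengths),
                   as.integer(chrom_lengths)),
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  body <- sprintf("%s\t%d\t%s\t%s\t%s\t.\tPASS\t.",
                  variants$chrom, variants$pos0 + 1L, variants$id,
                  variants$ref, variants$alt)
  writeLines(c(hdr, body), path)
}

write_mirna_fasta <- function(mirnas, path) {
  lines <- as.vector(rbind(
    sprintf(">%s|%s|%s", mirnas$accession, mirnas$name, mirnas$species),
    mirnas$mature_seq))
  writeLines(lines, path)
}

read_mirna_fasta <- function(path) {
  seqs <- Biostrings::readBStringSet(path)
  hdr <- strsplit(names(seqs), "|", fixed = TRUE)
  tibble(accession = vapply(hdr, `[`, character(1), 1),
         name = vapply(hdr, `[`, character(1), 2),
         species = vapply(hdr, `[`, character(1), 3),
         mature_seq = unname(norm_rna(as.character(seqs))))
}

#' Read a written bundle back through the io_formats loaders
#'
#' @param dir directory produced by [write_bundle()].
#' @return a `mirsitevar_bundle` (truth tables included when present).
#' @export
read_bundle <- function(dir) {
  p <- function(f) file.path(dir, f)
  transcripts <- load_utr_annotations(p("utr.gff3"), format = "gff3")
  chrom_tab <- read_tsv_file(p("chromosomes.tsv"))
  pred_files <- list.files(dir, pattern = "^pred_.*\\.tsv$")
  tools <- sub("^pred_(.*)\\.tsv$", "\\1", pred_files)
  paths <- setNames(file.path(dir, pred_files), tools)
  utr_tab <- read_tsv_file(p("utr_sequences.tsv"))
  truth <- NULL
  if (file.exists(p("truth_manifest.tsv"))) {
    truth <- list(
      conserved_impaired = read_tsv_file(p("truth_manifest.tsv")),
      true_sites = read_tsv_file(p("truth_sites.tsv")),
      disrupted = read_tsv_file(p("truth_disrupted.tsv")),
      conserved_mirnas = read_tsv_file(p("truth_conserved_mirnas.tsv")),
      upregulated = read_tsv_file(p("truth_upregulated.tsv"))
    )
  }
  structure(list(
    chrom_lengths = setNames(as.integer(chrom_tab$length), chrom_tab$chrom),
    transcripts = transcripts,
    gene_bodies = read_tsv_file(p("genes.tsv")),
    utr_seqs = setNames(utr_tab$sequence, utr_tab$transcript_id),
    mirnas = load_mirnas(p("mirnas.fa"), p("mirna_counts.tsv")),
    human_mirnas = read_mirna_fasta(p("human_mirnas.fa")),
    predictions = load_prediction_tables(paths),
    variants = load_variants(p("variants.vcf")),
    qtls = load_qtl_table(p("qtl.tsv")),
    expression = load_expression_table(p("expression.tsv")),
    orthologs = load_ortholog_table(p("orthologs.tsv")),
    mirsnp = load_mirsnp_table(p("mirsnp.tsv")),
    phenotypes = load_phenotype_table(p("phenotypes.tsv")),
    validated_pairs = read_tsv_file(p("validated.tsv")),
    truth = truth, config = NULL, seed = NA_integer_
  ), class = "mirsitevar_bundle")
}
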