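# Readers and writers for every external format the pipeline touches.
#
# All coordinates are normalised on ingest to a single internal convention:
# 0-based, half-open [start, end). GFF3 (1-based inclusive) and VCF POS
# (1-based) are shifted; BED is taken natively. Transcript 3'UTR models are
# tibbles with one row per transcript and a `blocks` list-column holding the
# UTR exon intervals ordered 5' -> 3' in *transcript* orientation (so on the
# minus strand the genomically last exon comes first).

#' Construct a transcript 3'UTR model table
#'
#' @param gene_id,transcript_id character vectors, one entry per transcript.
#' @param chrom,strand chromosome and strand (`+`/`-`) per transcript.
#' @param blocks list of data frames with 0-based half-open `start`/`end`
#'   columns, ordered 5' to 3' in transcript orientation.
#' @return A tibble with class `transcript_models`.
#' @export
transcript_models <- function(gene_id, transcript_id, chrom, strand, blocks) {
  stopifnot(length(gene_id) == length(transcript_id),
            length(blocks) == length(transcript_id))
  for (i in seq_along(blocks)) {
    b <- blocks[[i]]
    check_interval(b$start, b$end, sprintf("UTR block of %s", transcript_id[i]))
  }
  out <- tibble(
    gene_id = as.character(gene_id),
    transcript_id = as.character(transcript_id),
    chrom = as.character(chrom),
    strand = as.character(strand),
    blocks = lapply(blocks, function(b) {
      tibble::new_tibble(list(start = as.integer(b$start),
                              end = as.integer(b$end)),
                         nrow = length(b$start))
    })
  )
  class(out) <- c("transcript_models", class(out))
  out
}

#' Total 3'UTR length of each transcript model
#' @param transcripts a `transcript_models` tibble.
#' @return integer vector of summed block widths.
#' @export
utr_length <- function(transcripts) {
  vapply(transcripts$blocks, function(b) sum(b$end - b$start), integer(1))
}

order_blocks_tx <- function(df, strand) {
  df <- df[order(df$start), , drop = FALSE]
  if (strand == "-") df <- df[rev(seq_len(nrow(df))), , drop = FALSE]
  df
}

#' Load 3'UTR annotations from GFF3 or BED12
#'
#' GFF3 input must carry `three_prime_UTR` features with a `Parent` transcript
#' attribute and a `gene_id` attribute. BED12 input encodes one transcript per
#' line with UTR exons as blocks and `name` formatted `transcript|gene`.
#' Transcripts announced in a GFF3 (`mRNA`/`transcript` features) that carry
#' no 3'UTR feature are skipped with a warning.
#'
#' @param path file path.
#' @param format `"auto"` (by extension), `"gff3"` or `"bed"`.
#' @return A `transcript_models` tibble.
#' @export
load_utr_annotations <- function(path, format = c("auto", "gff3", "bed")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.bed$", path, ignore.case = TRUE)) "bed" else "gff3"
  }
  lines <- readLines(path, warn = FALSE)
  body <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (!length(body)) {
    warning("no annotation records in ", path)
    return(transcript_models(character(), character(), character(),
                             character(), list()))
  }
  nfield <- lengths(strsplit(body, "\t", fixed = TRUE))
  want <- if (format == "gff3") 9L else 12L
  if (any(nfield != want)) {
    line_no <- which(!startsWith(lines, "#") & nzchar(lines))[which(nfield != want)[1]]
    stop_ctx("malformed %s line %d in %s: expected %d tab-separated fields, got %d",
             format, line_no, path, want, nfield[nfield != want][1])
  }
  if (format == "gff3") load_utr_gff3(path) else load_utr_bed12(path)
}

load_utr_gff3 <- function(path) {
  g <- rtracklayer::import(path, format = "gff3")
  is_utr <- as.character(g$type) == "three_prime_UTR"
  announced <- unique(as.character(g$ID[as.character(g$type) %in%
                                          c("mRNA", "transcript")]))
  u <- g[is_utr]
  parent <- vapply(as.list(u$Parent), function(p) p[1], character(1))
  gene <- if (!is.null(u$gene_id)) as.character(u$gene_id) else parent
  df <- tibble(
    transcript_id = parent,
    gene_id = gene,
    chrom = as.character(GenomicRanges::seqnames(u)),
    strand = as.character(GenomicRanges::strand(u)),
    start = GenomicRanges::start(u) - 1L,  # 1-based inclusive -> 0-based
    end = GenomicRanges::end(u)
  )
  missing_utr <- setdiff(announced, unique(df$transcript_id))
  if (length(missing_utr)) {
    warning(length(missing_utr), " transcript(s) without 3'UTR features skipped")
  }
  if (!nrow(df)) {
    warning("no three_prime_UTR features in ", path)
    return(transcript_models(character(), character(), character(),
                             character(), list()))
  }
  build_models_from_blocks(df)
}

load_utr_bed12 <- function(path) {
  b <- rtracklayer::import(path, format = "bed")
  name <- as.character(b$name)
  parts <- strsplit(name, "|", fixed = TRUE)
  blk <- rtracklayer::blocks(b)
  df <- tibble(
    transcript_id = rep(vapply(parts, `[`, character(1), 1), lengths(blk)),
    gene_id = rep(vapply(parts, function(p) p[min(2, length(p))], character(1)),
                  lengths(blk)),
    chrom = as.character(GenomicRanges::seqnames(unlist(blk))),
    strand = rep(as.character(GenomicRanges::strand(b)), lengths(blk)),
    start = GenomicRanges::start(unlist(blk)) - 1L,
    end = GenomicRanges::end(unlist(blk))
  )
  build_models_from_blocks(df)
}

build_models_from_blocks <- function(df) {
  split_idx <- split(seq_len(nrow(df)), df$transcript_id)
  tx_ids <- names(split_idx)
  gene <- chrom <- strand <- character(length(tx_ids))
  blocks <- vector("list", length(tx_ids))
  for (i in seq_along(split_idx)) {
    rows <- df[split_idx[[i]], , drop = FALSE]
    if (length(unique(rows$chrom)) > 1 || length(unique(rows$strand)) > 1) {
      stop_ctx("transcript %s has UTR blocks on mixed chrom/strand", tx_ids[i])
    }
    ord <- order_blocks_tx(rows[, c("start", "end")], rows$strand[1])
    if (nrow(ord) > 1) {
      s <- sort(ord$start)
      e <- sort(ord$end)
      if (any(s[-1] < e[-length(e)])) {
        stop_ctx("transcript %s has overlapping UTR blocks", tx_ids[i])
      }
    }
    gene[i] <- rows$gene_id[1]
    chrom[i] <- rows$chrom[1]
    strand[i] <- rows$strand[1]
    blocks[[i]] <- ord
  }
  transcript_models(gene, tx_ids, chrom, strand, blocks)
}

#' Load single-nucleotide variants from a VCF file
#'
#' POS is converted to 0-based `pos0`, multi-allelic records are split into
#' one row per ALT allele, and non-SNV records (indels, symbolic alleles) are
#' dropped; the number dropped is reported as a message and attached as the
#' `dropped_non_snv` attribute. When genotype columns are present, per-strain
#' presence flags (`strain_<name>`) record whether the strain carries the ALT
#' allele; with `require_homozygous = TRUE` only homozygous ALT calls count
#' and variants carried by no strain are removed.
#'
#' @param path VCF 4.x file (uncompressed or bgzipped).
#' @param require_homozygous keep only variants homozygous in >= 1 strain.
#' @return tibble with columns chrom, pos0, id, ref, alt (+ strain flags).
#' @export
load_variants <- function(path, require_homozygous = FALSE) {
  v <- tryCatch(
    vcfR::read.vcfR(path, verbose = FALSE),
    error = function(e) stop_ctx("VCF parse error in %s: %s", path,
                                 conditionMessage(e))
  )
  fix <- v@fix
  if (is.null(fix) || !nrow(fix)) {
    return(tibble(chrom = character(), pos0 = integer(), id = character(),
                  ref = character(), alt = character()))
  }
  alts <- strsplit(fix[, "ALT"], ",", fixed = TRUE)
  n_alt <- lengths(alts)
  idx <- rep(seq_len(nrow(fix)), n_alt)
  out <- tibble(
    chrom = fix[idx, "CHROM"],
    pos0 = as.integer(fix[idx, "POS"]) - 1L,
    id = ifelse(is.na(fix[idx, "ID"]), NA_character_, fix[idx, "ID"]),
    ref = toupper(fix[idx, "REF"]),
    alt = toupper(unlist(alts)),
    .rec = idx
  )
  is_snv <- nchar(out$ref) == 1L & nchar(out$alt) == 1L &
    out$ref %in% c("A", "C", "G", "T") & out$alt %in% c("A", "C", "G", "T") &
    out$ref != out$alt
  n_drop <- sum(!is_snv)
  out <- out[is_snv, , drop = FALSE]

  gt <- v@gt
  if (!is.null(gt) && ncol(gt) > 1) {
    strains <- colnames(gt)[-1]
    gtm <- vcfR::extract.gt(v, element = "GT")
    for (s in strains) {
      calls <- gtm[out$.rec, s]
      present <- if (require_homozygous) {
        calls %in% c("1/1", "1|1")
      } else {
        grepl("1", calls, fixed = TRUE)
      }
      out[[paste0("strain_", s)]] <- !is.na(present) & present
    }
    if (require_homozygous) {
      flag_cols <- paste0("strain_", strains)
      keep <- rowSums(as.matrix(out[, flag_cols])) > 0
      out <- out[keep, , drop = FALSE]
    }
  }
  out$.rec <- NULL
  if (n_drop > 0) message(n_drop, " non-SNV record(s) dropped")
  attr(out, "dropped_non_snv") <- n_drop
  out
}

#' Load per-tool binding-site prediction tables
#'
#' Each TSV must expose columns mappable to (mirna, transcript_id, utr_start,
#' utr_end, score); the mapping and the coordinate base are declared per tool
#' in `dialects`. Duplicate rows within one tool's file are removed.
#'
#' @param paths named character vector, tool name -> TSV path.
#' @param roster character vector of allowed tool names; defaults to
#'   `names(paths)`. Tools outside the roster raise an error.
#' @param dialects optional named list; per tool a list with elements
#'   `col_map` (named character vector internal -> file column) and
#'   `coord_base` (0 or 1, default 0). 1-based inclusive coordinates are
#'   converted to the internal 0-based half-open convention.
#' @return tibble (tool, mirna, transcript_id, utr_start, utr_end, score)
#'   with the tool roster attached as attribute `roster`.
#' @export
load_prediction_tables <- function(paths, roster = names(paths),
                                   dialects = NULL) {
  unknown <- setdiff(names(paths), roster)
  if (length(unknown)) {
    stop_ctx("unknown prediction tool(s) not in roster: %s",
             paste(unknown, collapse = ", "))
  }
  default_map <- c(mirna = "mirna", transcript_id = "transcript_id",
                   utr_start = "utr_start", utr_end = "utr_end",
                   score = "score")
  out <- lapply(names(paths), function(tool) {
    d <- dialects[[tool]] %||% list()
    col_map <- d$col_map %||% default_map
    base <- d$coord_base %||% 0L
    df <- read.delim(paths[[tool]], stringsAsFactors = FALSE,
                     check.names = FALSE)
    missing <- setdiff(unname(col_map), names(df))
    if (length(missing)) {
      stop_ctx("tool %s: missing column(s) %s", tool,
               paste(missing, collapse = ", "))
    }
    res <- tibble(
      tool = tool,
      mirna = as.character(df[[col_map[["mirna"]]]]),
      transcript_id = as.character(df[[col_map[["transcript_id"]]]]),
      utr_start = as.integer(df[[col_map[["utr_start"]]]]),
      utr_end = as.integer(df[[col_map[["utr_end"]]]]),
      score = as.numeric(df[[col_map[["score"]]]])
    )
    if (base == 1L) {  # 1-based inclusive -> 0-based half-open
      res$utr_start <- res$utr_start - 1L
    }
    distinct(res)
  })
  out <- bind_rows(out)
  check_interval(out$utr_start, out$utr_end, "prediction site")
  attr(out, "roster") <- roster
  out
}

# ---- simple headered TSVs ----------------------------------------------

read_tsv_checked <- function(path, required, what) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop_ctx("%s table %s: missing column(s) %s", what, path,
             paste(missing, collapse = ", "))
  }
  as_tibble(df)
}

#' Load a per-tissue differential-expression table
#'
#' Required columns: gene_id, tissue, log2fc, pvalue. P-values outside [0, 1]
#' are rejected with the offending row number.
#' @param path TSV path.
#' @return validated tibble.
#' @export
load_expression_table <- function(path) {
  df <- read_tsv_checked(path, c("gene_id", "tissue", "log2fc", "pvalue"),
                         "expression")
  bad <- which(!is.finite(df$pvalue) | df$pvalue < 0 | df$pvalue > 1)
  if (length(bad)) stop_ctx("expression table %s: pvalue out of [0,1] at row %d",
                            path, bad[1])
  df
}

#' Load a QTL interval table
#'
#' BED-like TSV with columns qtl_id, chrom, start, end (0-based half-open),
#' trait, category (obesity/diabetes), lod. LOD must be non-negative.
#' @param path TSV path.
#' @return validated tibble.
#' @export
load_qtl_table <- function(path) {
  df <- read_tsv_checked(path, c("qtl_id", "chrom", "start", "end",
                                 "trait", "category", "lod"), "QTL")
  check_interval(df$start, df$end, "QTL interval")
  bad <- which(!is.finite(df$lod) | df$lod < 0)
  if (length(bad)) stop_ctx("QTL table %s: negative/missing LOD at row %d",
                            path, bad[1])
  df
}

#' Load a MirSNP-style table of human variants in predicted miRNA sites
#' @param path TSV with columns variant_id, human_gene, human_mirna,
#'   effect_class.
#' @return tibble.
#' @export
load_mirsnp_table <- function(path) {
  read_tsv_checked(path, c("variant_id", "human_gene", "human_mirna",
                           "effect_class"), "MirSNP")
}

#' Load a mouse-to-human ortholog map (many-to-many pairs are kept)
#' @param path TSV with columns mouse_gene, human_gene.
#' @return tibble of distinct pairs.
#' @export
load_ortholog_table <- function(path) {
  distinct(read_tsv_checked(path, c("mouse_gene", "human_gene"), "ortholog"))
}

#' Load a phenotype/GWAS/eQTL annotation table
#' @param path TSV with columns gene_id, source, term. `source` must be one
#'   of IMPC, MGI, GWAS, eQTL, validated_interaction, PubMed.
#' @return tibble.
#' @export
load_phenotype_table <- function(path) {
  df <- read_tsv_checked(path, c("gene_id", "source", "term"), "phenotype")
  allowed <- c("IMPC", "MGI", "GWAS", "eQTL", "validated_interaction", "PubMed")
  bad <- which(!df$source %in% allowed)
  if (length(bad)) stop_ctx("phenotype table %s: unknown source at row %d",
                            path, bad[1])
  df
}

#' Load mature miRNA sequences with read counts
#'
#' FASTA headers are `accession|name|species`; read counts come from a TSV
#' (accession, read_count). Sequences are normalised to the RNA alphabet and
#' must be 16-30 nt of unambiguous A/C/G/U.
#'
#' @param fasta_path mature-sequence FASTA.
#' @param counts_path TSV with columns accession, read_count.
#' @return tibble (accession, name, species, mature_seq, read_count).
#' @export
load_mirnas <- function(fasta_path, counts_path) {
  seqs <- Biostrings::readBStringSet(fasta_path)
  hdr <- strsplit(names(seqs), "|", fixed = TRUE)
  df <- tibble(
    accession = vapply(hdr, `[`, character(1), 1),
    name = vapply(hdr, function(h) h[min(2, length(h))], character(1)),
    species = vapply(hdr, function(h) h[min(3, length(h))], character(1)),
    mature_seq = unname(norm_rna(as.character(seqs)))
  )
  lens <- nchar(df$mature_seq)
  bad <- which(lens < 16 | lens > 30 | grepl("[^ACGU]", df$mature_seq))
  if (length(bad)) stop_ctx("miRNA %s: sequence fails length/alphabet invariant",
                            df$accession[bad[1]])
  counts <- read_tsv_checked(counts_path, c("accession", "read_count"),
                             "miRNA read-count")
  bad <- which(!is.finite(counts$read_count) | counts$read_count < 0)
  if (length(bad)) stop_ctx("read-count table: negative count at row %d", bad[1])
  out <- left_join(df, counts, by = "accession")
  out$read_count[is.na(out$read_count)] <- 0L
  out
}

# ---- writers -------------------------------------------------------------

#' Write a tibble as a plain TSV (the package's interchange format)
#' @param df data frame. @param path output path.
#' @return `path`, invisibly.
#' @export
write_tsv_file <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv_file <- function(path) {
  as_tibble(read.delim(path, stringsAsFactors = FALSE, check.names = FALSE))
}
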