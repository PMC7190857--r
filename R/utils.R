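# Internal helpers shared across modules.

# Reverse complement of an RNA string (vectorised over a character vector).
rc_rna <- function(x) {
  comp <- chartr("ACGU", "UGCA", x)
  vapply(strsplit(comp, "", fixed = TRUE),
         function(ch) paste(rev(ch), collapse = ""), character(1))
}

# Normalise a nucleotide string to the RNA alphabet (T -> U, upper case).
norm_rna <- function(x) chartr("T", "U", toupper(x))

# Normalise to DNA (U -> T), e.g. for VCF alleles.
norm_dna <- function(x) chartr("U", "T", toupper(x))

stop_ctx <- function(...) stop(sprintf(...), call. = FALSE)

check_interval <- function(start, end, what = "interval") {
  bad <- which(!(start >= 0 & end > start))
  if (length(bad)) {
    stop_ctx("%s invariant violated (need 0 <= start < end) at row %d",
             what, bad[1])
  }
  invisible(TRUE)
}

# GRanges from 0-based half-open columns.
granges0 <- function(chrom, start0, end0, strand = "*") {
  GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = start0 + 1L, end = end0),
    strand = strand
  )
}

seq_chunk <- function(n, size) split(seq_len(n), ceiling(seq_len(n) / size))
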