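# Shared fixtures: a reduced synthetic configuration for fast unit tests
# and a lazily generated bundle reused across test files.

small_config <- function(...) {
  synth_config(n_genes = 60, chrom_length = 1.5e6, n_mirnas = 12,
               n_qtl = 2, qtl_width = 2e5, n_decoy_qtl = 1,
               n_human_extra = 5, n_background_mirsnp = 40, ...)
}

.fixture_env <- new.env(parent = emptyenv())

small_bundle <- function() {
  if (is.null(.fixture_env$bundle)) {
    .fixture_env$bundle <- generate_bundle(small_config(), seed = 42)
  }
  .fixture_env$bundle
}

# a tiny hand-built transcript set: one single-block plus-strand, one
# single-block minus-strand, one two-block plus-strand transcript
toy_transcripts <- function() {
  transcript_models(
    gene_id = c("gA", "gB", "gC"),
    transcript_id = c("tA", "tB", "tC"),
    chrom = c("chr1", "chr1", "chr2"),
    strand = c("+", "-", "+"),
    blocks = list(
      data.frame(start = 1000L, end = 1200L),
      data.frame(start = 1000L, end = 1200L),
      # 5' block (60,64) then 3' block (80,90) in transcript orientation
      data.frame(start = c(60L, 80L), end = c(64L, 90L))
    )
  )
}
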