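# Projection of UTR-relative binding sites to genomic coordinates and
# intersection with variants.
#
# A UTR interval is mapped through the transcript's ordered UTR blocks: on
# the minus strand, transcript-ascending positions map to genome-descending
# positions, and a site spanning a UTR intron projects to several genomic
# blocks whose lengths sum to the site length. Containment of a variant in a
# site is tested in genomic space with an interval index (GenomicRanges);
# any SNP inside a consensus site counts as a potential disruption — no
# seed-pairing re-scoring is applied. A stricter `in_seed_region` flag
# (offset within the 8 nt at the site's 3' end, where the miRNA seed pairs)
# is emitted as an extra column but never filtered on.

#' Project a UTR-relative interval to genomic coordinates
#'
#' @param transcript one row of a `transcript_models` tibble.
#' @param utr_start,utr_end 0-based half-open interval on the concatenated
#'   3'UTR (transcript orientation).
#' @return tibble (chrom, start, end, strand) of 1..k genomic blocks, ordered
#'   in transcript orientation; block lengths sum to the interval length.
#' @export
project_utr_to_genomic <- function(transcript, utr_start, utr_end) {
  blocks <- transcript$blocks[[1]]
  strand <- transcript$strand
  check_interval(utr_start, utr_end, "UTR interval")
  widths <- blocks$end - blocks$start
  total <- sum(widths)
  if (utr_end > total) {
    stop_ctx("UTR interval [%d,%d) exceeds UTR length %d of %s",
             utr_start, utr_end, total, transcript$transcript_id)
  }
  cum <- cumsum(c(0L, widths))
  out <- vector("list", nrow(blocks))
  for (i in seq_len(nrow(blocks))) {
    lo <- max(utr_start, cum[i])
    hi <- min(utr_end, cum[i + 1])
    if (lo >= hi) next
    off0 <- lo - cum[i]
    off1 <- hi - cum[i]
    if (strand == "-") {
      g0 <- blocks$end[i] - off1
      g1 <- blocks$end[i] - off0
    } else {
      g0 <- blocks$start[i] + off0
      g1 <- blocks$start[i] + off1
    }
    out[[i]] <- tibble(chrom = transcript$chrom, start = g0, end = g1,
                       strand = strand)
  }
  bind_rows(out)
}

# Project all consensus sites of all transcripts at once. Returns one row per
# projected genomic block with the owning site's identity and the UTR offset
# of the block's first base (transcript orientation).
project_sites <- function(sites, transcripts) {
  if (!nrow(sites)) {
    return(tibble(site_id = integer(), mirna = character(),
                  transcript_id = character(), gene_id = character(),
                  chrom = character(), strand = character(),
                  start = integer(), end = integer(),
                  utr_start = integer(), utr_end = integer(),
                  block_utr_off = integer()))
  }
  tx_index <- match(sites$transcript_id, transcripts$transcript_id)
  if (anyNA(tx_index)) {
    stop_ctx("site refers to unknown transcript %s",
             sites$transcript_id[which(is.na(tx_index))[1]])
  }
  map <- utr_position_map(transcripts)
  blk_rows <- split(seq_len(nrow(map)), map$transcript_id)
  tx_len <- vapply(blk_rows, function(r) {
    sum(map$end[r] - map$start[r])
  }, integer(1))
  over <- which(sites$utr_end > tx_len[sites$transcript_id])
  if (length(over)) {
    stop_ctx("site [%d,%d) exceeds UTR length of %s",
             sites$utr_start[over[1]], sites$utr_end[over[1]],
             sites$transcript_id[over[1]])
  }
  nblk <- lengths(blk_rows)[sites$transcript_id]
  si <- rep(seq_len(nrow(sites)), nblk)
  bi <- unlist(blk_rows[sites$transcript_id], use.names = FALSE)
  w <- map$end[bi] - map$start[bi]
  lo <- pmax(sites$utr_start[si], map$tx_off[bi])
  hi <- pmin(sites$utr_end[si], map$tx_off[bi] + w)
  keep <- lo < hi
  si <- si[keep]; bi <- bi[keep]; lo <- lo[keep]; hi <- hi[keep]
  off0 <- lo - map$tx_off[bi]
  off1 <- hi - map$tx_off[bi]
  minus <- map$strand[bi] == "-"
  g0 <- ifelse(minus, map$end[bi] - off1, map$start[bi] + off0)
  g1 <- ifelse(minus, map$end[bi] - off0, map$start[bi] + off1)
  ord <- order(si, lo)  # transcript orientation within each site
  si <- si[ord]; bi <- bi[ord]
  tibble(
    site_id = si,
    mirna = sites$mirna[si],
    transcript_id = sites$transcript_id[si],
    gene_id = transcripts$gene_id[tx_index[si]],
    chrom = map$chrom[bi],
    strand = map$strand[bi],
    start = as.integer(g0[ord]), end = as.integer(g1[ord]),
    utr_start = sites$utr_start[si], utr_end = sites$utr_end[si],
    block_utr_off = as.integer(lo[ord] - sites$utr_start[si])
  )
}

#' Intersect variants with consensus binding sites
#'
#' One hit is produced per (variant, site) containment pair; a variant inside
#' sites of two miRNAs yields two hits (interaction-level accounting).
#'
#' @param variants tibble (chrom, pos0, id, ref, alt) from [load_variants()].
#' @param consensus a `consensus_interactions` object.
#' @param transcripts `transcript_models` tibble.
#' @param seed_region_width width (nt) of the 3'-terminal portion of the site
#'   treated as the seed-pairing region for the informational flag.
#' @return tibble of site-variant hits: mirna, transcript_id, gene_id,
#'   chrom, site_start, site_end (genomic span), site_utr_start, site_utr_end,
#'   variant position/alleles/id, offset_in_site (0-based, transcript
#'   orientation) and in_seed_region.
#' @export
intersect_variants_with_sites <- function(variants, consensus, transcripts,
                                          seed_region_width = 8L) {
  proj <- project_sites(consensus$sites, transcripts)
  empty <- tibble(
    mirna = character(), transcript_id = character(), gene_id = character(),
    chrom = character(), site_start = integer(), site_end = integer(),
    site_utr_start = integer(), site_utr_end = integer(),
    pos0 = integer(), ref = character(), alt = character(), id = character(),
    offset_in_site = integer(), in_seed_region = logical()
  )
  if (!nrow(proj) || !nrow(variants)) return(empty)
  site_gr <- granges0(proj$chrom, proj$start, proj$end)
  var_gr <- granges0(variants$chrom, variants$pos0, variants$pos0 + 1L)
  ov <- GenomicRanges::findOverlaps(var_gr, site_gr, ignore.strand = TRUE)
  if (!length(ov)) return(empty)
  vi <- S4Vectors::queryHits(ov)
  bi <- S4Vectors::subjectHits(ov)
  pos <- variants$pos0[vi]
  # block_utr_off is measured from the site start, so this is offset-in-site.
  offset <- ifelse(proj$strand[bi] == "-",
                   proj$block_utr_off[bi] + (proj$end[bi] - 1L - pos),
                   proj$block_utr_off[bi] + (pos - proj$start[bi]))
  site_len <- proj$utr_end[bi] - proj$utr_start[bi]
  span <- site_span(proj)
  hits <- tibble(
    mirna = proj$mirna[bi],
    transcript_id = proj$transcript_id[bi],
    gene_id = proj$gene_id[bi],
    chrom = proj$chrom[bi],
    site_start = span$start[match(bi, span$row)],
    site_end = span$end[match(bi, span$row)],
    site_utr_start = proj$utr_start[bi],
    site_utr_end = proj$utr_end[bi],
    pos0 = pos,
    ref = variants$ref[vi],
    alt = variants$alt[vi],
    id = if ("id" %in% names(variants)) variants$id[vi] else NA_character_,
    offset_in_site = as.integer(offset),
    in_seed_region = offset >= pmax(0L, site_len - seed_region_width)
  )
  stopifnot(all(hits$offset_in_site >= 0),
            all(hits$offset_in_site < site_len))
  arrange(hits, .data$chrom, .data$pos0, .data$mirna, .data$transcript_id)
}

# genomic span (min start, max end) of each site, indexed by projected row
site_span <- function(proj) {
  sp_start <- tapply(proj$start, proj$site_id, min)
  sp_end <- tapply(proj$end, proj$site_id, max)
  tibble(row = seq_len(nrow(proj)),
         start = as.integer(sp_start[as.character(proj$site_id)]),
         end = as.integer(sp_end[as.character(proj$site_id)]))
}

#' SNP-frequency track: variants within a symmetric flank of each position
#'
#' Counts variants v with |v.pos0 - position| <= flank on the same
#' chromosome (closed window, strand-agnostic).
#'
#' @param variants tibble with chrom, pos0.
#' @param positions optional tibble (chrom, position); when omitted, a grid
#'   with step `bin` is laid over each chromosome up to `chrom_lengths`
#'   (else up to the last variant).
#' @param flank window half-width in bp (default 50000).
#' @param bin grid step for the genome-wide track (default 100000).
#' @param chrom_lengths optional named vector of chromosome lengths.
#' @return tibble (chrom, position, count).
#' @export
snp_frequency_track <- function(variants, positions = NULL, flank = 50000L,
                                bin = 100000L, chrom_lengths = NULL) {
  stopifnot(flank >= 0)
  if (is.null(positions)) {
    chroms <- if (!is.null(chrom_lengths)) names(chrom_lengths) else
      sort(unique(variants$chrom))
    positions <- bind_rows(lapply(chroms, function(ch) {
      len <- if (!is.null(chrom_lengths)) chrom_lengths[[ch]] else
        max(variants$pos0[variants$chrom == ch], 0L)
      tibble(chrom = ch, position = seq(0L, as.integer(len), by = as.integer(bin)))
    }))
  }
  counts <- integer(nrow(positions))
  for (ch in unique(positions$chrom)) {
    vp <- sort(variants$pos0[variants$chrom == ch])
    sel <- which(positions$chrom == ch)
    if (!length(vp)) { counts[sel] <- 0L; next }
    p <- positions$position[sel]
    counts[sel] <- findInterval(p + flank, vp) -
      findInterval(p - flank - 1L, vp)
  }
  tibble(chrom = positions$chrom, position = positions$position,
         count = counts)
}

#' Distinct genes carrying at least one site-variant hit
#' @param hits tibble from [intersect_variants_with_sites()].
#' @return character vector of gene identifiers.
#' @export
genes_with_impaired_sites <- function(hits) {
  sort(unique(hits$gene_id))
}
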