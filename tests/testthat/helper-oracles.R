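# Independent brute-force oracles used to validate the fast implementations.
# These deliberately use the most naive formulation available (nested loops,
# exhaustive enumeration, direct tail summation) and never share code with
# the package paths they check.

# nested-loop interval containment: variant pos0 inside any projected block
brute_hits <- function(var_chrom, var_pos, blk_chrom, blk_start, blk_end) {
  out <- list()
  for (i in seq_along(var_pos)) {
    for (j in seq_along(blk_start)) {
      if (var_chrom[i] == blk_chrom[j] &&
          var_pos[i] >= blk_start[j] && var_pos[i] < blk_end[j]) {
        out[[length(out) + 1L]] <- c(i, j)
      }
    }
  }
  if (!length(out)) return(matrix(integer(0), ncol = 2))
  do.call(rbind, out)
}

# double-loop recount of distinct-tool support per (mirna, transcript)
brute_support <- function(predictions) {
  pairs <- unique(predictions[, c("mirna", "transcript_id")])
  support <- integer(nrow(pairs))
  tools <- unique(predictions$tool)
  for (i in seq_len(nrow(pairs))) {
    cnt <- 0L
    for (tl in tools) {
      found <- FALSE
      for (j in seq_len(nrow(predictions))) {
        if (predictions$tool[j] == tl &&
            predictions$mirna[j] == pairs$mirna[i] &&
            predictions$transcript_id[j] == pairs$transcript_id[i]) {
          found <- TRUE
          break
        }
      }
      if (found) cnt <- cnt + 1L
    }
    support[i] <- cnt
  }
  pairs$support <- support
  pairs
}

# Venn region counts via explicit set algebra
brute_venn <- function(sets) {
  k <- length(sets)
  nm <- names(sets)
  out <- list()
  for (mask in 1:(2^k - 1)) {
    members <- nm[bitwAnd(mask, 2^(seq_len(k) - 1)) > 0]
    inside <- Reduce(intersect, sets[members])
    for (other in setdiff(nm, members)) inside <- setdiff(inside, sets[[other]])
    out[[paste(members, collapse = "&")]] <- length(inside)
  }
  out
}

# hypergeometric upper tail by direct summation of the pmf
brute_hyper_tail <- function(N, nA, nB, k) {
  total <- 0
  for (i in k:min(nA, nB)) {
    total <- total + choose(nA, i) * choose(N - nA, nB - i) / choose(N, nB)
  }
  total
}

# two-sided Fisher p by enumeration over all tables with the observed margins
brute_fisher <- function(a, b, c, d) {
  r1 <- a + b; c1 <- a + c; n <- a + b + c + d
  prob <- function(x) {
    choose(c1, x) * choose(n - c1, r1 - x) / choose(n, r1)
  }
  p_obs <- prob(a)
  total <- 0
  for (x in max(0, r1 + c1 - n):min(r1, c1)) {
    px <- prob(x)
    if (px <= p_obs * (1 + 1e-7)) total <- total + px
  }
  min(1, total)
}

# exhaustive local alignment: best global alignment over all substring pairs,
# scored by plain recursion (no DP table)
brute_local_score <- function(a, b, match = 1, mismatch = -1, gap = -2) {
  a <- strsplit(a, "")[[1]]
  b <- strsplit(b, "")[[1]]
  glob <- function(x, y) {
    if (!length(x) && !length(y)) return(0)
    best <- -Inf
    if (length(x) && length(y)) {
      s <- if (x[1] == y[1]) match else mismatch
      best <- max(best, s + glob(x[-1], y[-1]))
    }
    if (length(x)) best <- max(best, gap + glob(x[-1], y))
    if (length(y)) best <- max(best, gap + glob(x, y[-1]))
    best
  }
  best <- 0
  for (i1 in seq_along(a)) for (i2 in i1:length(a)) {
    for (j1 in seq_along(b)) for (j2 in j1:length(b)) {
      best <- max(best, glob(a[i1:i2], b[j1:j2]))
    }
  }
  best
}

# connected components by union-find over an edge list
brute_components <- function(node_ids, from, to) {
  parent <- stats::setNames(node_ids, node_ids)
  find <- function(x) {
    while (parent[[x]] != x) x <- parent[[x]]
    x
  }
  for (e in seq_along(from)) {
    ra <- find(from[e]); rb <- find(to[e])
    if (ra != rb) parent[[ra]] <- rb
  }
  roots <- vapply(node_ids, find, character(1))
  unname(sort(table(roots), decreasing = TRUE))
}

# naive window count for the SNP-frequency track
brute_window_count <- function(var_chrom, var_pos, chrom, position, flank) {
  sum(var_chrom == chrom & abs(var_pos - position) <= flank)
}
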