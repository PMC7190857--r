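# Synthetic input bundles with planted signal and a truth manifest.
#
# The generator emulates the study conditions end to end: a small two-
# chromosome genome with 3'UTR-bearing genes, mature miRNAs with read
# counts, true binding sites planted as exact complements of each miRNA's
# 7mer seed (positions 2-8) so that a naive scanner can rediscover them,
# five per-tool prediction tables (true sites kept with per-tool sensitivity
# p_t plus Poisson false sites), strain variants at a baseline density that
# is multiplied inside QTL, tissue expression with up-regulation enriched
# among genes owning a disrupted site, and a mirrored human side (seed-
# conserved miRNA copies, an ortholog map, MirSNP-style records covering a
# stated fraction of disrupted-and-conserved interactions). Every planted
# quantity is recorded in the truth manifest for recovery testing.
#
# One global random stream is used, seeded once; sub-generators draw in a
# fixed order so adding an output never perturbs earlier ones.

#' Configuration for the synthetic bundle generator
#'
#' Defaults are scaled for desk tests (a full pipeline run takes seconds):
#' 2 chromosomes x 5 Mb, 300 genes, 50 miRNAs, 4 significant QTL of 500 kb
#' (plus 2 sub-threshold decoys), SNP density 1/350 bp, QTL SNP multiplier
#' 2.5, per-tool sensitivity 0.95 and 0.5 false sites per transcript.
#'
#' @param n_chromosomes,chrom_length genome shape.
#' @param n_genes number of genes (one transcript each).
#' @param utr_length_range min/max 3'UTR length (nt).
#' @param two_block_utr_frac fraction of UTRs split into two exons.
#' @param n_mirnas,mirna_length miRNA library shape.
#' @param p_unexpressed fraction of miRNAs with read count <= 5.
#' @param target_frac per-miRNA probability that a given gene is a target.
#' @param site_flank nt added on each side of the 7mer seed match to form
#'   the reported site footprint (miRanda-style ~21 nt sites).
#' @param tools tool roster. @param site_tool the site-defining tool.
#' @param p_tool named per-tool sensitivity for true sites.
#' @param f_tool named per-tool expected false sites per transcript.
#' @param snp_density baseline SNPs per bp.
#' @param qtl_snp_multiplier SNP-density multiplier inside significant QTL.
#' @param n_qtl,qtl_width,n_decoy_qtl significant and sub-threshold QTL.
#' @param tissues tissue labels.
#' @param p_upregulated_given_hit,p_upregulated_baseline per-tissue
#'   probability of up-regulation for genes with/without a disrupted site.
#' @param ortholog_fraction fraction of genes with a human ortholog.
#' @param seed_conserved_fraction fraction of miRNAs mirrored in human with
#'   the seed intact.
#' @param n_human_extra additional human miRNAs with non-matching seeds.
#' @param mirsnp_coverage fraction of disrupted-and-conserved interactions
#'   that receive a MirSNP-style record.
#' @param n_background_mirsnp unrelated MirSNP records.
#' @param validated_fraction fraction of true sites flagged as
#'   experimentally validated interactions.
#' @param characterized_fraction fraction of genes characterized per
#'   knockout source.
#' @param p_metabolic_hit,p_metabolic_other probability that a characterized
#'   gene shows a metabolic knockout phenotype, for genes with/without a
#'   disrupted site.
#' @return a validated `synth_config` list.
#' @export
synth_config <- function(n_chromosomes = 2, chrom_length = 5e6,
                         n_genes = 300,
                         utr_length_range = c(500, 1500),
                         two_block_utr_frac = 0.2,
                         n_mirnas = 50, mirna_length = 22,
                         p_unexpressed = 0.15,
                         target_frac = 0.2,
                         site_flank = 7,
                         tools = c("miranda", "targetscan", "pita",
                                   "rnahybrid", "mirdb"),
                         site_tool = "miranda",
                         p_tool = NULL, f_tool = NULL,
                         snp_density = 1 / 350,
                         qtl_snp_multiplier = 2.5,
                         n_qtl = 4, qtl_width = 5e5, n_decoy_qtl = 2,
                         tissues = c("gWAT", "BAT", "liver", "muscle"),
                         p_upregulated_given_hit = 0.5,
                         p_upregulated_baseline = 0.15,
                         ortholog_fraction = 0.8,
                         seed_conserved_fraction = 0.6,
                         n_human_extra = 20,
                         mirsnp_coverage = 0.8,
                         n_background_mirsnp = 200,
                         validated_fraction = 0.1,
                         characterized_fraction = 0.6,
                         p_metabolic_hit = 0.35,
                         p_metabolic_other = 0.15) {
  cfg <- as.list(environment())
  cfg$p_tool <- p_tool %||% setNames(rep(0.95, length(tools)), tools)
  cfg$f_tool <- f_tool %||% setNames(rep(0.5, length(tools)), tools)
  probs <- c(cfg$p_tool, cfg$f_tool >= 0, p_unexpressed, target_frac,
             p_upregulated_given_hit, p_upregulated_baseline,
             ortholog_fraction, seed_conserved_fraction, mirsnp_coverage,
             validated_fraction, characterized_fraction,
             p_metabolic_hit, p_metabolic_other)
  if (any(probs < 0 | probs > 1)) stop_ctx("probabilities must be in [0,1]")
  if (qtl_snp_multiplier < 1) stop_ctx("qtl_snp_multiplier must be >= 1")
  if (snp_density <= 0) stop_ctx("snp_density must be > 0")
  if (!site_tool %in% tools) stop_ctx("site_tool must be in the roster")
  per_chrom <- ceiling((n_qtl + n_decoy_qtl) / n_chromosomes)
  if (per_chrom * qtl_width * 2 > chrom_length) {
    stop_ctx("QTL do not fit the chromosomes; shrink n_qtl or qtl_width")
  }
  class(cfg) <- "synth_config"
  cfg
}

RNA_BASES <- c("A", "C", "G", "U")
COMP_DNA <- c(A = "T", C = "G", G = "C", U = "A")

rand_rna <- function(n) sample(RNA_BASES, n, replace = TRUE)

#' Generate a complete synthetic input bundle with truth manifest
#'
#' Deterministic given (config, seed): the same pair always yields the same
#' bundle, record for record.
#'
#' @param config a [synth_config()].
#' @param seed integer seed for the single global random stream.
#' @return a `mirsitevar_bundle` list: transcripts, gene_bodies, utr_seqs,
#'   mirnas, human_mirnas, predictions, variants, qtls, expression,
#'   orthologs, mirsnp, phenotypes, validated_pairs, truth (manifest),
#'   config, seed.
#' @export
generate_bundle <- function(config = synth_config(), seed = 1L) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(seed)
  cfg <- config

  # --- genome and genes --------------------------------------------------
  chroms <- paste0("chr", seq_len(cfg$n_chromosomes))
  chrom_len <- setNames(rep(as.integer(cfg$chrom_length),
                            cfg$n_chromosomes), chroms)
  per_chrom <- diff(floor(seq(0, cfg$n_genes, length.out =
                                cfg$n_chromosomes + 1)))
  gene_id <- sprintf("g%03d", seq_len(cfg$n_genes))
  gene_chrom <- rep(chroms, per_chrom)
  slot <- floor(cfg$chrom_length / max(per_chrom))
  gene_len <- sample(8000:25000, cfg$n_genes, replace = TRUE)
  slot_index <- unlist(lapply(per_chrom, seq_len)) - 1L
  gene_start <- as.integer(slot_index * slot +
                             floor(runif(cfg$n_genes) *
                                     (slot - gene_len - 1L)))
  gene_end <- gene_start + gene_len
  gene_strand <- sample(c("+", "-"), cfg$n_genes, replace = TRUE)
  gene_bodies <- tibble(gene_id = gene_id, chrom = gene_chrom,
                        start = gene_start, end = gene_end,
                        strand = gene_strand)

  utr_len <- sample(cfg$utr_length_range[1]:cfg$utr_length_range[2],
                    cfg$n_genes, replace = TRUE)
  two_block <- runif(cfg$n_genes) < cfg$two_block_utr_frac
  intron_len <- ifelse(two_block, sample(200:1000, cfg$n_genes,
                                         replace = TRUE), 0L)
  split_frac <- runif(cfg$n_genes, 0.3, 0.7)
  blocks <- vector("list", cfg$n_genes)
  for (i in seq_len(cfg$n_genes)) {
    L <- utr_len[i]
    if (!two_block[i]) {
      blocks[[i]] <- if (gene_strand[i] == "+") {
        tibble(start = gene_end[i] - L, end = gene_end[i])
      } else {
        tibble(start = gene_start[i], end = gene_start[i] + L)
      }
    } else {
      l1 <- as.integer(floor(L * split_frac[i])); l2 <- L - l1
      I <- intron_len[i]
      if (gene_strand[i] == "+") {
        # 5' block first in transcript orientation
        b2 <- c(gene_end[i] - l2, gene_end[i])
        b1 <- c(b2[1] - I - l1, b2[1] - I)
        blocks[[i]] <- tibble(start = c(b1[1], b2[1]), end = c(b1[2], b2[2]))
      } else {
        b2 <- c(gene_start[i], gene_start[i] + l2)        # 3'-most (low coords)
        b1 <- c(b2[2] + I, b2[2] + I + l1)                # 5' block
        blocks[[i]] <- tibble(start = c(b1[1], b2[1]), end = c(b1[2], b2[2]))
      }
    }
  }
  transcripts <- transcript_models(gene_id, paste0(gene_id, ".t1"),
                                   gene_chrom, gene_strand, blocks)
  tx_of_gene <- setNames(transcripts$transcript_id, transcripts$gene_id)

  utr_chars <- lapply(utr_len, rand_rna)
  names(utr_chars) <- transcripts$transcript_id

  # --- miRNAs ------------------------------------------------------------
  m_acc <- sprintf("MIMAT%06d", seq_len(cfg$n_mirnas))
  m_name <- sprintf("mmu-miR-%d-5p", 100 + seq_len(cfg$n_mirnas))
  m_seq <- vapply(seq_len(cfg$n_mirnas),
                  function(i) paste(rand_rna(cfg$mirna_length), collapse = ""),
                  character(1))
  unexpr <- runif(cfg$n_mirnas) < cfg$p_unexpressed
  read_count <- ifelse(unexpr, sample(0:5, cfg$n_mirnas, replace = TRUE),
                       6L + stats::rnbinom(cfg$n_mirnas, mu = 200, size = 2))
  mirnas <- tibble(accession = m_acc, name = m_name, species = "mmu",
                   mature_seq = m_seq, read_count = as.integer(read_count))

  # --- plant true binding sites -----------------------------------------
  n_targets <- rbinom(cfg$n_mirnas, cfg$n_genes, cfg$target_frac)
  site_pairs <- bind_rows(lapply(seq_len(cfg$n_mirnas), function(i) {
    tibble(mirna = m_acc[i],
           gene_id = sort(sample(gene_id, n_targets[i])))
  }))
  fl <- as.integer(cfg$site_flank)
  seed_rc_chars <- lapply(m_seq, function(s)
    strsplit(rc_rna(substr(s, 2, 7 + 1)), "", fixed = TRUE)[[1]])
  names(seed_rc_chars) <- m_acc
  occupied <- lapply(utr_len, function(L) matrix(integer(0), ncol = 2))
  names(occupied) <- transcripts$transcript_id
  gidx <- match(site_pairs$gene_id, gene_id)
  n_pairs <- nrow(site_pairs)
  pl_ok <- logical(n_pairs)
  pl_seed <- integer(n_pairs)
  for (k in seq_len(n_pairs)) {
    tx <- tx_of_gene[[site_pairs$gene_id[k]]]
    L <- utr_len[gidx[k]]
    occ <- occupied[[tx]]
    for (try in 1:10) {
      s <- fl + sample.int(L - 7L - 2L * fl, 1) - 1L
      f0 <- s - fl; f1 <- s + 7L + fl
      if (!nrow(occ) || all(f1 <= occ[, 1] | f0 >= occ[, 2])) {
        occupied[[tx]] <- rbind(occ, c(f0, f1))
        utr_chars[[tx]][(s + 1L):(s + 7L)] <-
          seed_rc_chars[[site_pairs$mirna[k]]]
        pl_ok[k] <- TRUE
        pl_seed[k] <- s
        break
      }
    }
  }
  true_sites <- tibble(mirna = site_pairs$mirna[pl_ok],
                       transcript_id = unname(
                         tx_of_gene[site_pairs$gene_id[pl_ok]]),
                       gene_id = site_pairs$gene_id[pl_ok],
                       seed_utr_start = pl_seed[pl_ok],
                       utr_start = pl_seed[pl_ok] - fl,
                       utr_end = pl_seed[pl_ok] + 7L + fl)
  utr_seqs <- vapply(utr_chars, paste, character(1), collapse = "")

  # --- per-tool prediction tables ---------------------------------------
  pred <- vector("list", length(cfg$tools))
  for (t in seq_along(cfg$tools)) {
    tool <- cfg$tools[t]
    keep <- runif(nrow(true_sites)) < cfg$p_tool[[tool]]
    kept <- true_sites[keep, c("mirna", "transcript_id",
                               "utr_start", "utr_end")]
    n_false <- rpois(1, cfg$f_tool[[tool]] * cfg$n_genes)
    f_tx <- sample(transcripts$transcript_id, n_false, replace = TRUE)
    f_len <- 7L + 2L * fl
    f_start <- as.integer(floor(runif(n_false) *
                                  (utr_len[match(f_tx,
                                                 transcripts$transcript_id)] -
                                     f_len)))
    false_sites <- tibble(mirna = sample(m_acc, n_false, replace = TRUE),
                          transcript_id = f_tx,
                          utr_start = f_start, utr_end = f_start + f_len)
    tab <- bind_rows(kept, false_sites)
    tab$tool <- tool
    tab$score <- if (tool == "miranda") round(runif(nrow(tab), 140, 190), 2)
                 else round(runif(nrow(tab)), 4)
    pred[[t]] <- tab[, c("tool", "mirna", "transcript_id",
                         "utr_start", "utr_end", "score")]
  }
  predictions <- distinct(bind_rows(pred))
  attr(predictions, "roster") <- cfg$tools

  # --- QTL ---------------------------------------------------------------
  n_all_qtl <- cfg$n_qtl + cfg$n_decoy_qtl
  q_chrom <- rep(chroms, length.out = n_all_qtl)
  q_slot <- floor(cfg$chrom_length / ceiling(n_all_qtl / cfg$n_chromosomes))
  q_rank <- unlist(lapply(table(factor(q_chrom, levels = chroms)), seq_len)) - 1L
  q_start <- as.integer(q_rank * q_slot +
                          floor(runif(n_all_qtl) * (q_slot - cfg$qtl_width)))
  traits <- c("body weight", "blood glucose", "total fat mass",
              "plasma insulin", "liver triglycerides", "lean mass")
  is_sig <- seq_len(n_all_qtl) <= cfg$n_qtl
  qtls <- tibble(qtl_id = sprintf("qtl%d", seq_len(n_all_qtl)),
                 chrom = q_chrom,
                 start = q_start,
                 end = q_start + as.integer(cfg$qtl_width),
                 trait = sample(traits, n_all_qtl, replace = TRUE),
                 category = rep(c("obesity", "diabetes"),
                                length.out = n_all_qtl),
                 lod = round(ifelse(is_sig, runif(n_all_qtl, 3.5, 8),
                                    runif(n_all_qtl, 1, 2.9)), 2))

  # --- variants ----------------------------------------------------------
  sig_qtl <- qtls[is_sig, , drop = FALSE]
  var_rows <- list()
  for (ch in chroms) {
    qs <- sig_qtl[sig_qtl$chrom == ch, , drop = FALSE]
    qs <- qs[order(qs$start), , drop = FALSE]
    bounds <- sort(unique(c(0L, qs$start, qs$end, chrom_len[[ch]])))
    for (si in seq_len(length(bounds) - 1)) {
      s0 <- bounds[si]; s1 <- bounds[si + 1]
      in_qtl <- any(qs$start <= s0 & qs$end >= s1)
      rate <- cfg$snp_density * if (in_qtl) cfg$qtl_snp_multiplier else 1
      n <- rpois(1, (s1 - s0) * rate)
      n <- min(n, s1 - s0)
      if (n > 0) {
        pos <- s0 + sort(sample.int(s1 - s0, n)) - 1L
        var_rows[[length(var_rows) + 1L]] <- tibble(chrom = ch, pos0 = pos)
      }
    }
  }
  variants <- bind_rows(var_rows)
  variants <- arrange(variants, match(.data$chrom, chroms), .data$pos0)
  variants$id <- sprintf("mv%07d", seq_len(nrow(variants)))

  # reference alleles: consistent with the UTR sequence where applicable
  utr_map <- utr_position_map(transcripts)
  variants$ref <- sample(c("A", "C", "G", "T"), nrow(variants),
                         replace = TRUE)
  ov <- GenomicRanges::findOverlaps(
    granges0(variants$chrom, variants$pos0, variants$pos0 + 1L),
    granges0(utr_map$chrom, utr_map$start, utr_map$end),
    ignore.strand = TRUE)
  vi <- S4Vectors::queryHits(ov); bi <- S4Vectors::subjectHits(ov)
  utr_pos <- ifelse(utr_map$strand[bi] == "-",
                    utr_map$tx_off[bi] + (utr_map$end[bi] - 1L -
                                            variants$pos0[vi]),
                    utr_map$tx_off[bi] + (variants$pos0[vi] -
                                            utr_map$start[bi]))
  base_rna <- substr(utr_seqs[utr_map$transcript_id[bi]],
                     utr_pos + 1L, utr_pos + 1L)
  genome_base <- ifelse(utr_map$strand[bi] == "-",
                        COMP_DNA[base_rna], norm_dna(base_rna))
  variants$ref[vi] <- unname(genome_base)
  alt_pool <- matrix(c("C","G","T", "A","G","T", "A","C","T", "A","C","G"),
                     nrow = 3,
                     dimnames = list(NULL, c("A", "C", "G", "T")))
  variants$alt <- alt_pool[cbind(sample.int(3, nrow(variants), replace = TRUE),
                                 match(variants$ref, colnames(alt_pool)))]
  variants <- variants[, c("chrom", "pos0", "id", "ref", "alt")]

  # variant UTR positions, kept for the truth computation (pure arithmetic
  # in UTR space; independent of the pipeline's genomic interval index)
  var_utr <- tibble(vrow = vi,
                    transcript_id = utr_map$transcript_id[bi],
                    utr_pos = as.integer(utr_pos))

  # --- truth: disrupted sites -------------------------------------------
  ts <- true_sites
  ts$site_row <- seq_len(nrow(ts))
  disrupted <- inner_join(var_utr, ts, by = "transcript_id",
                          relationship = "many-to-many")
  disrupted <- disrupted[disrupted$utr_pos >= disrupted$utr_start &
                           disrupted$utr_pos < disrupted$utr_end, ,
                         drop = FALSE]
  disrupted <- tibble(mirna = disrupted$mirna,
                      transcript_id = disrupted$transcript_id,
                      gene_id = disrupted$gene_id,
                      variant_id = variants$id[disrupted$vrow],
                      utr_start = disrupted$utr_start,
                      utr_end = disrupted$utr_end,
                      utr_pos = disrupted$utr_pos)

  expressed_acc <- mirnas$accession[mirnas$read_count > 5]
  hit_genes <- sort(unique(
    disrupted$gene_id[disrupted$mirna %in% expressed_acc]))

  # --- expression --------------------------------------------------------
  expr_rows <- vector("list", length(cfg$tissues))
  for (t in seq_along(cfg$tissues)) {
    p_up <- ifelse(gene_id %in% hit_genes,
                   cfg$p_upregulated_given_hit, cfg$p_upregulated_baseline)
    up <- runif(cfg$n_genes) < p_up
    lfc <- ifelse(up, abs(rnorm(cfg$n_genes, 1.5, 0.5)) + 0.7,
                  rnorm(cfg$n_genes, 0, 0.35))
    pv <- ifelse(up, runif(cfg$n_genes, 0, 0.05), runif(cfg$n_genes))
    expr_rows[[t]] <- tibble(gene_id = gene_id, tissue = cfg$tissues[t],
                             log2fc = round(lfc, 4), pvalue = round(pv, 6))
  }
  expression <- bind_rows(expr_rows)
  # realized up-regulated sets under the downstream filter definition
  up_truth <- expression[expression$pvalue <= 0.05 &
                           abs(expression$log2fc) >= 0.7 &
                           expression$log2fc > 0,
                         c("tissue", "gene_id")]

  # --- human mirror ------------------------------------------------------
  n_cons <- round(cfg$seed_conserved_fraction * cfg$n_mirnas)
  cons_idx <- sort(sample.int(cfg$n_mirnas, n_cons))
  h_seq <- m_seq[cons_idx]
  mut_positions <- setdiff(seq_len(cfg$mirna_length), 2:8)
  for (j in seq_along(h_seq)) {
    k <- sample(1:3, 1)
    at <- sample(mut_positions, k)
    ch <- strsplit(h_seq[j], "", fixed = TRUE)[[1]]
    for (p in at) ch[p] <- sample(setdiff(RNA_BASES, ch[p]), 1)
    h_seq[j] <- paste(ch, collapse = "")
  }
  h_cons <- tibble(accession = sprintf("MIMAT9%05d", seq_len(n_cons)),
                   name = sub("mmu", "hsa", m_name[cons_idx]),
                   species = "hsa", mature_seq = h_seq)
  mouse_seeds <- substr(m_seq, 2, 8)
  extra_seq <- character(cfg$n_human_extra)
  for (j in seq_len(cfg$n_human_extra)) {
    repeat {
      s <- paste(rand_rna(cfg$mirna_length), collapse = "")
      if (!substr(s, 2, 8) %in% mouse_seeds) break
    }
    extra_seq[j] <- s
  }
  h_extra <- tibble(accession = sprintf("MIMAT8%05d",
                                        seq_len(cfg$n_human_extra)),
                    name = sprintf("hsa-miR-%d-3p",
                                   900 + seq_len(cfg$n_human_extra)),
                    species = "hsa", mature_seq = extra_seq)
  human_mirnas <- bind_rows(h_cons, h_extra)
  conserved_mirnas <- tibble(mouse_acc = m_acc[cons_idx],
                             mouse_name = m_name[cons_idx],
                             human_acc = h_cons$accession,
                             human_name = h_cons$name)

  # --- orthologs ---------------------------------------------------------
  orth_idx <- sort(sample.int(cfg$n_genes,
                              round(cfg$ortholog_fraction * cfg$n_genes)))
  orthologs <- tibble(mouse_gene = gene_id[orth_idx],
                      human_gene = paste0("h_", gene_id[orth_idx]))

  # --- MirSNP records ----------------------------------------------------
  dci <- disrupted |>
    inner_join(conserved_mirnas[, c("mouse_acc", "human_name")],
               by = c(mirna = "mouse_acc")) |>
    inner_join(orthologs, by = c(gene_id = "mouse_gene"))
  covered <- runif(nrow(dci)) < cfg$mirsnp_coverage
  dci_cov <- dci[covered, , drop = FALSE]
  rs_id <- sprintf("rs%07d", seq_len(nrow(dci_cov)))
  dci_cov$rs_id <- rs_id
  mirsnp_true <- tibble(variant_id = rs_id,
                        human_gene = dci_cov$human_gene,
                        human_mirna = dci_cov$human_name,
                        effect_class = sample(c("break", "decrease"),
                                              nrow(dci_cov), replace = TRUE))
  # background records must never coincide with a translated impaired pair
  forbidden <- unique(paste(dci$human_gene, dci$human_name))
  bg_gene <- sample(orthologs$human_gene, cfg$n_background_mirsnp,
                    replace = TRUE)
  bg_mirna <- sample(human_mirnas$name, cfg$n_background_mirsnp,
                     replace = TRUE)
  bg_keep <- !paste(bg_gene, bg_mirna) %in% forbidden
  mirsnp_bg <- tibble(
    variant_id = sprintf("rs9%06d", seq_len(sum(bg_keep))),
    human_gene = bg_gene[bg_keep],
    human_mirna = bg_mirna[bg_keep],
    effect_class = sample(c("break", "create", "enhance"), sum(bg_keep),
                          replace = TRUE))
  mirsnp <- bind_rows(mirsnp_true, mirsnp_bg)

  # --- phenotype / evidence tables --------------------------------------
  irrelevant_terms <- c("abnormal gait", "short tail", "kinked tail",
                        "abnormal coat color", "preweaning lethality",
                        "abnormal snout morphology", "hydrocephaly",
                        "abnormal ear shape", "cataract", "micropthalmia")
  ph_rows <- list()
  for (src in c("IMPC", "MGI")) {
    char_genes <- sort(sample(gene_id,
                              round(cfg$characterized_fraction * cfg$n_genes)))
    p_met <- ifelse(char_genes %in% hit_genes, cfg$p_metabolic_hit,
                    cfg$p_metabolic_other)
    met <- runif(length(char_genes)) < p_met
    term <- ifelse(met,
                   sample(impc_metabolic_terms(), length(char_genes),
                          replace = TRUE),
                   sample(irrelevant_terms, length(char_genes),
                          replace = TRUE))
    ph_rows[[src]] <- tibble(gene_id = char_genes, source = src, term = term)
  }
  for (src in c("GWAS", "eQTL", "PubMed")) {
    p_in <- switch(src, GWAS = c(0.25, 0.08), eQTL = c(0.15, 0.05),
                   PubMed = c(0.2, 0.1))
    p <- ifelse(gene_id %in% hit_genes, p_in[1], p_in[2])
    sel <- runif(cfg$n_genes) < p
    term <- switch(src,
                   GWAS = sample(c("BMI", "type 2 diabetes", "obesity"),
                                 sum(sel), replace = TRUE),
                   eQTL = sample(cfg$tissues, sum(sel), replace = TRUE),
                   PubMed = "literature")
    ph_rows[[src]] <- tibble(gene_id = gene_id[sel], source = src,
                             term = term)
  }
  phenotypes <- arrange(bind_rows(ph_rows), .data$source, .data$gene_id)

  n_val <- round(cfg$validated_fraction * nrow(true_sites))
  val_idx <- sort(sample.int(nrow(true_sites), n_val))
  validated_pairs <- distinct(tibble(mirna = true_sites$mirna[val_idx],
                                     gene_id = true_sites$gene_id[val_idx]))

  # --- truth: conserved impaired interactions ---------------------------
  genes_in_qtl <- gene_bodies$gene_id[overlaps_any(gene_bodies, sig_qtl)]
  up_by_gene <- split(up_truth$tissue, up_truth$gene_id)
  dci_cov$tissues <- vapply(as.character(dci_cov$gene_id), function(g) {
    paste(sort(unique(up_by_gene[[g]])), collapse = ",")
  }, character(1))
  truth_ci <- dci_cov[dci_cov$mirna %in% expressed_acc &
                        dci_cov$gene_id %in% genes_in_qtl &
                        nzchar(dci_cov$tissues), , drop = FALSE]
  truth_ci <- tibble(mouse_mirna = truth_ci$mirna,
                     human_mirna = truth_ci$human_name,
                     mouse_gene = truth_ci$gene_id,
                     human_gene = truth_ci$human_gene,
                     variant_id = truth_ci$rs_id,
                     mouse_variant = truth_ci$variant_id,
                     tissues = truth_ci$tissues)

  truth <- list(
    true_sites = true_sites,
    disrupted = disrupted,
    hit_genes = hit_genes,
    upregulated = up_truth,
    conserved_mirnas = conserved_mirnas,
    conserved_impaired = truth_ci,
    genes_in_qtl = genes_in_qtl,
    qtl_boosted = tibble(qtl_id = qtls$qtl_id, boosted = is_sig)
  )

  structure(list(
    chrom_lengths = chrom_len,
    transcripts = transcripts, gene_bodies = gene_bodies,
    utr_seqs = utr_seqs, mirnas = mirnas, human_mirnas = human_mirnas,
    predictions = predictions, variants = variants, qtls = qtls,
    expression = expression, orthologs = orthologs, mirsnp = mirsnp,
    phenotypes = phenotypes, validated_pairs = validated_pairs,
    truth = truth, config = cfg, seed = seed
  ), class = "mirsitevar_bundle")
}

overlaps_any <- function(gene_bodies, regions) {
  if (!nrow(regions)) return(rep(FALSE, nrow(gene_bodies)))
  g <- granges0(gene_bodies$chrom, gene_bodies$start, gene_bodies$end)
  q <- granges0(regions$chrom, regions$start, regions$end)
  GenomicRanges::countOverlaps(g, q, ignore.strand = TRUE) > 0
}

# flat table of UTR blocks with the transcript-orientation offset of each
# block's first base
utr_position_map <- function(transcripts) {
  nb <- vapply(transcripts$blocks, nrow, integer(1))
  start <- unlist(lapply(transcripts$blocks, `[[`, "start"),
                  use.names = FALSE)
  end <- unlist(lapply(transcripts$blocks, `[[`, "end"), use.names = FALSE)
  w <- end - start
  tx_off <- unlist(lapply(split(w, rep(seq_along(nb), nb)), function(x)
    cumsum(c(0L, x))[seq_along(x)]), use.names = FALSE)
  tibble(transcript_id = rep(transcripts$transcript_id, nb),
         chrom = rep(transcripts$chrom, nb),
         strand = rep(transcripts$strand, nb),
         start = as.integer(start), end = as.integer(end),
         tx_off = as.integer(tx_off))
}

#' Scan a UTR sequence for exact 7mer seed-complement matches
#'
#' Verification oracle for planted sites: returns every position where the
#' UTR contains the reverse complement of the miRNA's positions 2-8. This is
#' a naive scanner, not a target predictor.
#'
#' @param utr_seq UTR sequence (RNA or DNA alphabet).
#' @param mirna_seq mature miRNA sequence (>= 8 nt).
#' @return tibble (utr_start, utr_end), 0-based half-open.
#' @export
scan_seed_sites <- function(utr_seq, mirna_seq) {
  if (nchar(mirna_seq) < 8) stop_ctx("miRNA sequence must be >= 8 nt")
  pat <- rc_rna(substr(norm_rna(mirna_seq), 2, 8))
  hits <- gregexpr(pat, norm_rna(utr_seq), fixed = TRUE)[[1]]
  if (hits[1] == -1) {
    return(tibble(utr_start = integer(), utr_end = integer()))
  }
  tibble(utr_start = as.integer(hits) - 1L,
         utr_end = as.integer(hits) + 6L)
}
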