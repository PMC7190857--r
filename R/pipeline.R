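# End-to-end orchestration. analyze_bundle() runs the whole analysis on an
# in-memory bundle; run_pipeline() is the file-based driver that reads a
# written bundle, runs the same stages, writes every stage's TSV with a
# JSON sidecar (parameters + input checksums) and skips stages whose
# sidecar still matches (checksum-based resume).
#
# Stage order follows the identification funnel: expressed-miRNA filter ->
# consensus vote -> variant/site intersection -> tissue DE filter -> QTL
# assignment and enrichment -> cross-species conservation -> phenotype
# annotation and networks. Each filter only removes interactions, so the
# funnel counts are non-increasing.

#' Analysis parameters for the pipeline
#'
#' @param min_readcount expression filter threshold (read count strictly
#'   greater than this is kept).
#' @param min_support consensus vote threshold (distinct tools).
#' @param site_tool site-defining tool.
#' @param p_max,min_abs_log2fc DE filter thresholds (inclusive).
#' @param lod_min QTL significance threshold (LOD strictly above).
#' @param flank SNP-frequency window half-width (bp).
#' @param track_bin genome-wide SNP track grid step (bp).
#' @param align_match,align_mismatch,align_gap alignment scoring.
#' @param min_score minimum cross-species alignment score.
#' @param require_seed require 7mer seed identity for conservation.
#' @param universe_size gene universe for the hypergeometric overlap test
#'   (default: number of genes in the annotation).
#' @return a `pipeline_params` list.
#' @export
pipeline_params <- function(min_readcount = 5, min_support = 3,
                            site_tool = "miranda",
                            p_max = 0.05, min_abs_log2fc = 0.7,
                            lod_min = 3, flank = 50000L,
                            track_bin = 100000L,
                            align_match = 1, align_mismatch = -1,
                            align_gap = -2, min_score = 14,
                            require_seed = TRUE,
                            universe_size = NULL) {
  structure(as.list(environment()), class = "pipeline_params")
}

#' Run the full analysis on an in-memory bundle
#'
#' @param bundle a `mirsitevar_bundle`.
#' @param params a [pipeline_params()].
#' @param through last stage to execute: one of "consensus", "intersect",
#'   "enrichment", "conservation", "annotation" (default: everything).
#' @return list of stage results: expressed, consensus, hits, snp_track,
#'   up_sets, qtl_assign, candidates (per-tissue and union),
#'   venn_counts, enrichment_global, enrichment_per_qtl, overlap_test,
#'   alignments, conserved, tissue_counts, evidence, phenotype_tests,
#'   network, funnel (named counts), params.
#' @export
analyze_bundle <- function(bundle, params = pipeline_params(),
                           through = "annotation") {
  stages <- c("consensus", "intersect", "enrichment", "conservation",
              "annotation")
  through <- match.arg(through, stages)
  stage_n <- match(through, stages)
  res <- list(params = params)

  # 1-2: expressed miRNAs, consensus vote
  res$expressed <- filter_expressed_mirnas(bundle$mirnas,
                                           params$min_readcount)
  cons <- consensus_vote(bundle$predictions, res$expressed,
                         min_support = params$min_support,
                         site_tool = params$site_tool)
  cons <- attach_validation(cons, bundle$validated_pairs,
                            bundle$transcripts)
  res$consensus <- cons
  funnel <- c(n_mirnas = nrow(bundle$mirnas),
              n_mirnas_expressed = length(res$expressed),
              n_consensus_pairs = nrow(cons$pairs))
  if (stage_n < 2) { res$funnel <- funnel; return(res) }

  # 3: variant/site intersection
  hits <- intersect_variants_with_sites(bundle$variants, cons,
                                        bundle$transcripts)
  res$hits <- hits
  res$impaired_genes <- genes_with_impaired_sites(hits)
  res$snp_track <- snp_frequency_track(bundle$variants,
                                       flank = params$flank,
                                       bin = params$track_bin,
                                       chrom_lengths = bundle$chrom_lengths)
  pairs_with_snp <- distinct(hits, .data$mirna, .data$transcript_id)
  funnel <- c(funnel, n_pairs_with_snp = nrow(pairs_with_snp),
              n_site_snps = length(unique(hits$id)),
              n_hits = nrow(hits),
              n_genes_with_snp = length(res$impaired_genes))

  # 4-5: DE filter, QTL, enrichment
  res$up_sets <- filter_upregulated(bundle$expression,
                                    p_max = params$p_max,
                                    min_abs_log2fc = params$min_abs_log2fc,
                                    direction = "up")
  sig_q <- significant_qtl(bundle$qtls, params$lod_min)
  res$qtl_assign <- assign_genes_to_qtl(bundle$gene_bodies, sig_q)
  up_union <- unique(res$up_sets$gene_id)
  res$candidates <- res$up_sets |>
    filter(.data$gene_id %in% res$impaired_genes)
  cand_union <- unique(res$candidates$gene_id)
  in_qtl_genes <- res$qtl_assign$gene_id[res$qtl_assign$in_qtl]
  res$candidates_in_qtl <- res$candidates |>
    filter(.data$gene_id %in% in_qtl_genes)
  cand_qtl_union <- unique(res$candidates_in_qtl$gene_id)
  tissue_sets <- split(res$candidates_in_qtl$gene_id,
                       res$candidates_in_qtl$tissue)
  res$venn_counts <- if (length(tissue_sets) >= 1) {
    overlap_counts(tissue_sets)
  } else tibble(region = character(), count = integer())
  N <- params$universe_size %||% nrow(bundle$gene_bodies)
  res$overlap_test <- hypergeometric_overlap(
    N, length(up_union), length(res$impaired_genes),
    length(intersect(up_union, res$impaired_genes)))
  res$enrichment_global <- qtl_enrichment_suite(
    res$up_sets, res$impaired_genes, res$qtl_assign, scope = "global")
  res$enrichment_per_qtl <- qtl_enrichment_suite(
    res$up_sets, res$impaired_genes, res$qtl_assign, scope = "per-qtl")
  pairs_up <- distinct(hits[hits$gene_id %in% cand_union, ],
                       .data$mirna, .data$transcript_id)
  pairs_qtl <- distinct(hits[hits$gene_id %in% cand_qtl_union, ],
                        .data$mirna, .data$transcript_id)
  funnel <- c(funnel,
              n_genes_upregulated = length(up_union),
              n_pairs_candidate = nrow(pairs_up),
              n_genes_candidate = length(cand_union),
              n_pairs_candidate_in_qtl = nrow(pairs_qtl),
              n_genes_candidate_in_qtl = length(cand_qtl_union))
  if (stage_n < 4) { res$funnel <- funnel; return(res) }

  # 6: conservation
  res$alignments <- match_mirnas_cross_species(
    bundle$mirnas[bundle$mirnas$accession %in% res$expressed, ],
    bundle$human_mirnas,
    min_score = params$min_score, require_seed = params$require_seed,
    match = params$align_match, mismatch = params$align_mismatch,
    gap = params$align_gap)
  up_by_gene <- split(res$up_sets$tissue, res$up_sets$gene_id)
  mouse_hits <- hits |>
    filter(.data$gene_id %in% cand_qtl_union) |>
    distinct(.data$mirna, .data$gene_id, .data$id) |>
    mutate(tissues = vapply(.data$gene_id, function(g)
      paste(sort(unique(up_by_gene[[g]])), collapse = ","), character(1)))
  res$conserved <- conserved_impaired_interactions(
    mouse_hits[, c("mirna", "gene_id", "tissues")],
    bundle$orthologs, res$alignments, bundle$mirsnp)
  res$tissue_counts <- tissue_interaction_counts(res$conserved)
  funnel <- c(funnel,
              n_pairs_conserved = nrow(distinct(res$conserved,
                                                .data$mouse_mirna,
                                                .data$mouse_gene)),
              n_genes_conserved = length(unique(res$conserved$mouse_gene)))
  if (stage_n < 5) { res$funnel <- funnel; return(res) }

  # 7: annotation and networks
  res$evidence <- screen_phenotype_terms(
    bundle$phenotypes[bundle$phenotypes$source %in% c("IMPC", "MGI"), ])
  cons_genes <- unique(res$conserved$mouse_gene)
  tests <- lapply(c("IMPC", "MGI"), function(src) {
    ev <- res$evidence[res$evidence$source == src, ]
    tab <- phenotype_contingency(cons_genes, ev$gene_id, ev)
    if (attr(tab, "untestable")) {
      return(tibble(label = src, a = tab$a, b = tab$b, c = tab$c, d = tab$d,
                    statistic = NA_real_, p_chi2 = NA_real_,
                    p_fisher = NA_real_, odds_ratio = NA_real_,
                    exp_a = NA_real_, exp_b = NA_real_, exp_c = NA_real_,
                    exp_d = NA_real_))
    }
    enrichment_2x2(tab, label = src)
  })
  res$phenotype_tests <- bind_rows(tests)
  all_ev <- bind_rows(
    res$evidence[, c("gene_id", "source", "metabolic_flag")],
    tibble(gene_id = bundle$phenotypes$gene_id[
             bundle$phenotypes$source %in% c("GWAS", "eQTL", "PubMed")],
           source = bundle$phenotypes$source[
             bundle$phenotypes$source %in% c("GWAS", "eQTL", "PubMed")],
           metabolic_flag = TRUE))
  res$evidence_venn <- evidence_overlap_counts(
    all_ev[all_ev$gene_id %in% cons_genes, ])
  pheno_links <- phenotype_link_table(bundle$phenotypes, res$evidence,
                                      cons_genes)
  res$network <- build_network(res$conserved, pheno_links,
                               bundle$validated_pairs)
  res$funnel <- funnel
  res
}

# gene -> phenotype/eQTL/GWAS-trait node links for the network, restricted
# to the conserved candidate genes
phenotype_link_table <- function(phenotypes, evidence, genes) {
  met <- evidence[evidence$metabolic_flag & evidence$gene_id %in% genes, ]
  ko <- if (nrow(met)) {
    tibble(gene_id = rep(met$gene_id,
                         lengths(strsplit(met$terms, ",", fixed = TRUE))),
           node = unlist(strsplit(met$terms, ",", fixed = TRUE)),
           node_type = "phenotype")
  } else tibble(gene_id = character(), node = character(),
                node_type = character())
  ko <- ko[tolower(ko$node) %in% tolower(impc_metabolic_terms()), ,
           drop = FALSE]
  other <- phenotypes[phenotypes$source %in% c("GWAS", "eQTL") &
                        phenotypes$gene_id %in% genes, , drop = FALSE]
  oth <- tibble(gene_id = other$gene_id,
                node = paste0(ifelse(other$source == "GWAS", "GWAS:",
                                     "eQTL:"), other$term),
                node_type = as.character(ifelse(other$source == "GWAS",
                                                "GWAS-trait", "eQTL")))
  distinct(bind_rows(ko, oth))
}

#' Recovery of planted conserved-impaired interactions
#'
#' Runs the full analysis and compares recovered interactions against the
#' bundle's truth manifest at the (mouse miRNA, mouse gene, MirSNP variant)
#' level.
#'
#' @param bundle a `mirsitevar_bundle` with a truth manifest.
#' @param params a [pipeline_params()].
#' @return list(n_truth, n_found, tp, fp, fn, sensitivity, fdr).
#' @export
recovery_metrics <- function(bundle, params = pipeline_params()) {
  res <- analyze_bundle(bundle, params, through = "conservation")
  key <- function(df, m, g, v) paste(df[[m]], df[[g]], df[[v]], sep = "\r")
  found <- unique(key(res$conserved, "mouse_mirna", "mouse_gene",
                      "variant_id"))
  truth <- unique(key(bundle$truth$conserved_impaired, "mouse_mirna",
                      "mouse_gene", "variant_id"))
  tp <- length(intersect(found, truth))
  list(n_truth = length(truth), n_found = length(found),
       tp = tp, fp = length(found) - tp, fn = length(truth) - tp,
       sensitivity = if (length(truth)) tp / length(truth) else NA_real_,
       fdr = if (length(found)) 1 - tp / length(found) else 0)
}

# ---- file-based driver with checksum resume ----------------------------

stage_defs <- function() {
  list(
    consensus = c("utr.gff3", "mirnas.fa", "mirna_counts.tsv", "validated.tsv"),
    intersect = c("variants.vcf"),
    enrichment = c("expression.tsv", "qtl.tsv", "genes.tsv"),
    conservation = c("human_mirnas.fa", "orthologs.tsv", "mirsnp.tsv"),
    annotation = c("phenotypes.tsv")
  )
}

stage_param_names <- function() {
  list(
    consensus = c("min_readcount", "min_support", "site_tool"),
    intersect = c("flank", "track_bin"),
    enrichment = c("p_max", "min_abs_log2fc", "lod_min", "universe_size"),
    conservation = c("align_match", "align_mismatch", "align_gap",
                     "min_score", "require_seed"),
    annotation = character(0)
  )
}

stage_outputs <- function() {
  list(
    consensus = c("consensus_interactions.tsv"),
    intersect = c("site_variant_hits.tsv", "snp_frequency.tsv"),
    enrichment = c("upregulated.tsv", "gene_qtl.tsv", "venn_counts.tsv",
                   "enrichment_global.tsv", "enrichment_per_qtl.tsv",
                   "overlap_test.tsv"),
    conservation = c("mirna_alignments.tsv", "conserved_interactions.tsv",
                     "sankey_counts.tsv"),
    annotation = c("evidence.tsv", "contingency_tables.tsv",
                   "evidence_venn.tsv", "network_nodes.tsv",
                   "network_edges.tsv", "components.tsv")
  )
}

#' Run the file-based pipeline over a written bundle
#'
#' Executes all stages in funnel order, writing each stage's TSV outputs to
#' `out_dir` together with a JSON sidecar recording the stage parameters
#' and md5 checksums of its input files. On a rerun, a stage whose sidecar
#' still matches (same parameters, same cumulative inputs) is skipped and
#' its cached outputs are reused; editing a parameter recomputes only that
#' stage and everything downstream.
#'
#' @param bundle_dir directory written by [write_bundle()].
#' @param out_dir output directory.
#' @param params a [pipeline_params()].
#' @return run report: list(stages = tibble(stage, status), funnel,
#'   report_path). The report is also written as `run_report.json`.
#' @export
run_pipeline <- function(bundle_dir, out_dir, params = pipeline_params()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  defs <- stage_defs()
  pnames <- stage_param_names()
  outs <- stage_outputs()
  stages <- names(defs)

  # cumulative signature: a stage depends on its own inputs/params and on
  # everything upstream
  sig <- ""
  status <- character(length(stages))
  need_run <- FALSE
  for (i in seq_along(stages)) {
    st <- stages[i]
    files <- file.path(bundle_dir, defs[[st]])
    sums <- tools::md5sum(files[file.exists(files)])
    psub <- params[pnames[[st]]]
    sig <- paste(sig, st, paste(names(sums), sums, collapse = ";"),
                 paste(names(psub), vapply(psub, function(x)
                   paste(format(x), collapse = ","), character(1)),
                   collapse = ";"),
                 sep = "|")
    side <- file.path(out_dir, paste0(st, ".json"))
    cached <- FALSE
    if (!need_run && file.exists(side)) {
      prev <- jsonlite::read_json(side)
      cached <- identical(prev$signature, sig) &&
        all(file.exists(file.path(out_dir, outs[[st]])))
    }
    if (cached) {
      status[i] <- "cached"
    } else {
      need_run <- TRUE
      status[i] <- "computed"
    }
    jsonlite::write_json(list(stage = st, signature = sig,
                              parameters = psub),
                         side, auto_unbox = TRUE, null = "null")
  }

  report_path <- file.path(out_dir, "run_report.json")
  if (!need_run && file.exists(report_path)) {
    prev <- jsonlite::read_json(report_path)
    return(list(stages = tibble(stage = stages, status = status),
                funnel = unlist(prev$funnel), report_path = report_path))
  }

  bundle <- read_bundle(bundle_dir)
  res <- analyze_bundle(bundle, params, through = "annotation")
  by_stage <- setNames(rep(stages, lengths(outs)), unlist(outs))
  w <- function(df, f) {
    # cached stages keep their outputs untouched
    if (status[match(by_stage[[f]], stages)] == "computed") {
      write_tsv_file(df, file.path(out_dir, f))
    }
  }
  w(cbind(res$consensus$pairs,
          dropped_no_site = res$consensus$dropped_no_site),
    "consensus_interactions.tsv")
  w(res$hits, "site_variant_hits.tsv")
  w(tibble(chrom = res$snp_track$chrom, start = res$snp_track$position,
           end = res$snp_track$position + 1L, count = res$snp_track$count),
    "snp_frequency.tsv")
  w(res$up_sets, "upregulated.tsv")
  w(res$qtl_assign, "gene_qtl.tsv")
  w(res$venn_counts, "venn_counts.tsv")
  w(res$enrichment_global, "enrichment_global.tsv")
  w(res$enrichment_per_qtl, "enrichment_per_qtl.tsv")
  w(res$overlap_test, "overlap_test.tsv")
  w(res$alignments, "mirna_alignments.tsv")
  w(res$conserved, "conserved_interactions.tsv")
  w(res$tissue_counts, "sankey_counts.tsv")
  w(res$evidence, "evidence.tsv")
  w(res$phenotype_tests, "contingency_tables.tsv")
  w(res$evidence_venn, "evidence_venn.tsv")
  w(res$network$nodes, "network_nodes.tsv")
  w(res$network$edges, "network_edges.tsv")
  w(res$network$components, "components.tsv")

  report <- list(stages = tibble(stage = stages, status = status),
                 funnel = res$funnel,
                 report_path = report_path)
  jsonlite::write_json(list(stages = stages, status = status,
                            funnel = as.list(res$funnel)),
                       report_path, auto_unbox = TRUE)
  report
}
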