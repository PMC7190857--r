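# Phenotype-term screening of knockout tables, contingency inputs for the
# knockout-phenotype enrichment, evidence Venn counts, and assembly of
# miRNA-gene-phenotype regulatory networks.

#' The 12 knockout phenotype terms treated as metabolically relevant
#'
#' The default relevant-term list for standardized knockout screens
#' (body weight, lean body mass, circulating metabolite levels, glucose
#' tolerance, ...). Editable: pass your own list to
#' [screen_phenotype_terms()]; non-standardized resources (MGI-style
#' free-text phenotypes) need a curated list supplied by the user.
#' @return character vector of 12 terms.
#' @export
impc_metabolic_terms <- function() {
  c("body weight", "lean body mass", "circulating triglyceride level",
    "circulating glucose level", "circulating cholesterol level",
    "total body fat amount", "circulating LDL/HDL cholesterol level",
    "circulating free fatty acid level", "circulating glycerol level",
    "circulating insulin level", "glucose tolerance",
    "fasted circulating glucose level")
}

#' Screen knockout phenotype tables for metabolically relevant terms
#'
#' A gene's `metabolic_flag` for a source is true iff any of its terms in
#' that source matches the source's relevant-term list (exact string match
#' after case folding).
#'
#' @param knockouts tibble (gene_id, source, term).
#' @param relevant_terms named list, source -> character vector of relevant
#'   terms; sources without an entry fall back to `default_terms`.
#' @param default_terms fallback term list ([impc_metabolic_terms()]).
#' @return tibble (gene_id, source, metabolic_flag, terms) — one row per
#'   (gene, source), `terms` comma-joined.
#' @export
screen_phenotype_terms <- function(knockouts,
                                   relevant_terms = list(),
                                   default_terms = impc_metabolic_terms()) {
  if (!nrow(knockouts)) {
    return(tibble(gene_id = character(), source = character(),
                  metabolic_flag = logical(), terms = character()))
  }
  fold <- function(x) tolower(trimws(x))
  knockouts |>
    group_by(.data$gene_id, .data$source) |>
    summarise(
      metabolic_flag = {
        rel <- relevant_terms[[.data$source[1]]] %||% default_terms
        any(fold(.data$term) %in% fold(rel))
      },
      terms = paste(sort(unique(.data$term)), collapse = ","),
      .groups = "drop"
    ) |>
    arrange(.data$gene_id, .data$source)
}

#' Knockout-phenotype enrichment contingency table for a candidate gene set
#'
#' Over the characterized genes of one knockout source, builds the 2x2 table
#' rows = (other phenotype, metabolic phenotype) x cols = (in candidate set,
#' rest). The margins reconcile with the input set sizes by construction.
#'
#' @param candidates character vector of candidate genes.
#' @param characterized character vector of genes characterized in the
#'   source (the universe of the test).
#' @param evidence tibble (gene_id, metabolic_flag) for that source.
#' @return a `contingency_2x2`; attribute `untestable` is TRUE when the
#'   candidate column is empty.
#' @export
phenotype_contingency <- function(candidates, characterized, evidence) {
  characterized <- unique(characterized)
  metabolic <- evidence$gene_id[evidence$metabolic_flag]
  in_cand <- characterized %in% candidates
  is_met <- characterized %in% metabolic
  tab <- contingency_2x2(a = sum(!is_met & in_cand),
                         b = sum(!is_met & !in_cand),
                         c = sum(is_met & in_cand),
                         d = sum(is_met & !in_cand))
  attr(tab, "untestable") <- sum(in_cand) == 0
  tab
}

#' Venn-region counts of evidence sources over a gene set
#'
#' Same partition semantics as [overlap_counts()], over the genes flagged by
#' each evidence source.
#'
#' @param evidence tibble (gene_id, source) or (gene_id, source,
#'   metabolic_flag); when the flag is present only flagged rows count for
#'   knockout sources.
#' @param sources which sources to compare (default GWAS, eQTL, knockout =
#'   IMPC|MGI, literature = PubMed).
#' @return tibble (region, count).
#' @export
evidence_overlap_counts <- function(evidence,
                                    sources = c("GWAS", "eQTL", "knockout",
                                                "literature")) {
  flag_ok <- if ("metabolic_flag" %in% names(evidence)) {
    evidence$metabolic_flag | !evidence$source %in% c("IMPC", "MGI")
  } else rep(TRUE, nrow(evidence))
  ev <- evidence[flag_ok, , drop = FALSE]
  pick <- function(src) unique(ev$gene_id[ev$source %in% src])
  sets <- lapply(sources, function(s) {
    switch(s,
           knockout = pick(c("IMPC", "MGI")),
           literature = pick("PubMed"),
           pick(s))
  })
  names(sets) <- sources
  overlap_counts(sets)
}

#' Assemble a miRNA-gene-phenotype regulatory network
#'
#' Nodes are typed (miRNA, gene, phenotype, eQTL, GWAS-trait); edges are
#' `impaired_binding` (miRNA -> gene, one per distinct conserved pair, with
#' a `validated` attribute for experimentally supported bindings) or
#' `phenotype_link` (gene -> phenotype/eQTL/GWAS-trait node). Type
#' constraints are enforced at construction. Connected components are
#' enumerated deterministically (largest first, ties by smallest member id).
#'
#' @param conserved tibble from [conserved_impaired_interactions()].
#' @param phenotype_links tibble (gene_id, node, node_type) with node_type
#'   in phenotype/eQTL/GWAS-trait; only genes present in `conserved` are
#'   linked (no orphan phenotype nodes).
#' @param validated_pairs optional tibble (mirna, gene_id) marking
#'   experimentally validated bindings.
#' @return list(nodes, edges, components): nodes (id, type), edges (from,
#'   to, type, validated), components (component_id, n_nodes, members).
#' @export
build_network <- function(conserved, phenotype_links = NULL,
                          validated_pairs = NULL) {
  pair <- distinct(tibble(mirna = conserved$mouse_mirna,
                          gene = conserved$mouse_gene))
  edges <- tibble(from = pair$mirna, to = pair$gene,
                  type = "impaired_binding", validated = FALSE)
  if (!is.null(validated_pairs) && nrow(validated_pairs)) {
    vkey <- paste(validated_pairs$mirna, validated_pairs$gene_id)
    edges$validated <- paste(edges$from, edges$to) %in% vkey
  }
  nodes <- bind_rows(tibble(id = unique(pair$mirna), type = "miRNA"),
                     tibble(id = unique(pair$gene), type = "gene"))
  if (!is.null(phenotype_links) && nrow(phenotype_links)) {
    ok_types <- c("phenotype", "eQTL", "GWAS-trait")
    bad <- setdiff(unique(phenotype_links$node_type), ok_types)
    if (length(bad)) stop_ctx("unknown phenotype node type: %s", bad[1])
    pl <- phenotype_links[phenotype_links$gene_id %in% pair$gene, ,
                          drop = FALSE]
    pl <- distinct(pl)
    if (nrow(pl)) {
      if (any(pl$node %in% nodes$id)) {
        stop_ctx("phenotype node id collides with a miRNA/gene id")
      }
      nodes <- bind_rows(nodes,
                         distinct(tibble(id = pl$node, type = pl$node_type)))
      edges <- bind_rows(edges,
                         tibble(from = pl$gene_id, to = pl$node,
                                type = "phenotype_link", validated = FALSE))
    }
  }
  validate_network_types(nodes, edges)
  comp <- network_components(nodes, edges)
  list(nodes = arrange(nodes, .data$type, .data$id),
       edges = arrange(edges, .data$type, .data$from, .data$to),
       components = comp)
}

validate_network_types <- function(nodes, edges) {
  type_of <- setNames(nodes$type, nodes$id)
  ib <- edges[edges$type == "impaired_binding", , drop = FALSE]
  if (nrow(ib) && (any(type_of[ib$from] != "miRNA") ||
                   any(type_of[ib$to] != "gene"))) {
    stop_ctx("impaired_binding edges must connect miRNA -> gene")
  }
  pl <- edges[edges$type == "phenotype_link", , drop = FALSE]
  if (nrow(pl) && (any(type_of[pl$from] != "gene") ||
                   any(type_of[pl$to] %in% c("gene", "miRNA")))) {
    stop_ctx("phenotype_link edges must connect gene -> non-gene")
  }
  orphan <- setdiff(nodes$id[!nodes$type %in% c("miRNA", "gene")],
                    c(edges$from, edges$to))
  if (length(orphan)) stop_ctx("orphan phenotype node: %s", orphan[1])
  invisible(TRUE)
}

network_components <- function(nodes, edges) {
  if (!nrow(nodes)) {
    return(tibble(component_id = integer(), n_nodes = integer(),
                  members = character()))
  }
  g <- igraph::graph_from_data_frame(
    d = edges[, c("from", "to")], directed = FALSE,
    vertices = nodes$id
  )
  cm <- igraph::components(g)$membership
  comp <- split(names(cm), cm)
  members <- vapply(comp, function(m) paste(sort(m), collapse = ","),
                    character(1))
  ord <- order(-lengths(comp), vapply(comp, function(m) min(sort(m)),
                                      character(1)))
  tibble(component_id = seq_along(ord),
         n_nodes = unname(lengths(comp)[ord]),
         members = unname(members[ord]))
}
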