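#' Build the prior degradation-pathway graph
#'
#' Scans all ordered pairs of protein records for sequence containment and
#' draws a degradation edge from the heavier containing protein to the
#' lighter contained fragment: intact subunit to primary degradation product,
#' and larger fragment to smaller (secondary) fragment. A fragment contained
#' in several candidate parents receives one edge from each ("and/or"
#' semantics); disambiguation is left to the modelling stage. A transitive
#' reduction is then applied to the degradation edges so that a secondary
#' product links to its immediate parent fragment rather than directly to the
#' intact subunit -- that stepwise structure is the pathway hypothesis.
#' Regulation edges (literature annotations such as subunit up-regulation or
#' self-feedback) are appended verbatim, never inferred from sequence.
#'
#' Pairs whose evidence kinds differ (peptides vs intervals) are not
#' comparable and yield no edge; [sequence_contained()] itself raises an
#' error for such a comparison.
#'
#' @param records A [protein_records()] table with unique ids.
#' @param regulation Optional data frame of regulation edges with columns
#'   `source`, `target` and optionally `evidence`. Self-edges are allowed.
#' @return A `pathway_graph`: list with `nodes` (tibble `id`, `tier`,
#'   `mass_kda`) and `edges` (tibble `source`, `target`, `kind`, `evidence`),
#'   degradation subgraph guaranteed acyclic.
#' @export
build_prior_graph <- function(records, regulation = NULL) {
  validate_protein_records(records)
  n <- nrow(records)
  src <- tgt <- character()
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      a <- records[i, ]
      b <- records[j, ]
      if (b$tier != "fragment") next
      if (evidence_kind(a$evidence[[1]]) != evidence_kind(b$evidence[[1]])) next
      contained <- sequence_contained(b, a)
      if (!contained) next
      if (a$mass_kda == b$mass_kda && sequence_contained(a, b)) {
        rlang::abort(paste0("cyclic degradation evidence: mutual containment ",
                            "with equal mass between ", a$id, " and ", b$id))
      }
      if (a$mass_kda > b$mass_kda) {
        src <- c(src, a$id)
        tgt <- c(tgt, b$id)
      }
    }
  }
  edges <- tibble::tibble(source = src, target = tgt,
                          kind = "degradation",
                          evidence = "sequence containment")
  edges <- transitive_reduction(edges)

  if (!is.null(regulation) && nrow(as.data.frame(regulation))) {
    reg <- tibble::as_tibble(regulation)
    if (!all(c("source", "target") %in% names(reg))) {
      rlang::abort("`regulation` needs columns `source` and `target`")
    }
    bad <- setdiff(unique(c(reg$source, reg$target)), records$id)
    if (length(bad)) {
      rlang::abort(paste0("regulation edges reference unknown proteins: ",
                          paste(bad, collapse = ", ")))
    }
    if (is.null(reg$evidence)) reg$evidence <- "literature annotation"
    reg$kind <- "regulation"
    edges <- dplyr::bind_rows(edges,
                              reg[, c("source", "target", "kind", "evidence")])
  }
  edges <- dplyr::arrange(edges, .data$kind, .data$source, .data$target)

  graph <- structure(
    list(nodes = tibble::tibble(id = records$id, tier = records$tier,
                                mass_kda = records$mass_kda),
         edges = edges),
    class = "pathway_graph"
  )
  stopifnot(degradation_is_dag(graph))
  graph
}

# remove degradation edges implied by a longer degradation path
transitive_reduction <- function(edges) {
  if (!nrow(edges)) return(edges)
  keep <- rep(TRUE, nrow(edges))
  adj <- split(edges$target, edges$source)
  reachable <- function(from, to, skip) {
    queue <- setdiff(adj[[from]], if (identical(from, skip$source)) skip$target)
    seen <- character()
    while (length(queue)) {
      v <- queue[1]
      queue <- queue[-1]
      if (v == to) return(TRUE)
      if (v %in% seen) next
      seen <- c(seen, v)
      queue <- c(queue, adj[[v]])
    }
    FALSE
  }
  for (k in seq_len(nrow(edges))) {
    e <- edges[k, ]
    if (reachable(e$source, e$target, e)) keep[k] <- FALSE
  }
  edges[keep, ]
}

degradation_is_dag <- function(graph) {
  ig <- as_igraph(graph, kind = "degradation")
  igraph::is_dag(ig)
}

#' Convert a pathway graph to igraph
#' @param graph A `pathway_graph`.
#' @param kind Restrict to `"degradation"` or `"regulation"` edges
#'   (default: all).
#' @return An [igraph::graph] with edge attribute `kind`.
#' @export
as_igraph <- function(graph, kind = NULL) {
  stopifnot(inherits(graph, "pathway_graph"))
  edges <- graph$edges
  if (!is.null(kind)) edges <- edges[edges$kind == kind, ]
  igraph::graph_from_data_frame(
    as.data.frame(edges),
    directed = TRUE,
    vertices = as.data.frame(graph$nodes)
  )
}

#' @export
print.pathway_graph <- function(x, ...) {
  cat("<pathway_graph> ", nrow(x$nodes), " proteins, ",
      sum(x$edges$kind == "degradation"), " degradation edges, ",
      sum(x$edges$kind == "regulation"), " regulation edges\n", sep = "")
  invisible(x)
}

#' Turn a pathway graph into an SEM skeleton
#'
#' One observed variable per protein, one free structural coefficient per
#' edge (degradation and regulation alike, including self-feedback loops),
#' a free disturbance variance per node. The result is the starting model of
#' the refinement loop.
#'
#' @param graph A `pathway_graph`.
#' @return A [sem_model()].
#' @export
to_sem_skeleton <- function(graph) {
  stopifnot(inherits(graph, "pathway_graph"))
  paths <- if (nrow(graph$edges)) {
    data.frame(from = graph$edges$source, to = graph$edges$target)
  } else {
    NULL
  }
  sem_model(paths = paths, observed = graph$nodes$id)
}

#' Write a pathway graph to standard graph formats
#'
#' @param graph A `pathway_graph`.
#' @param graphml,dot,json Optional output file paths; each format is written
#'   only when its path is non-`NULL`.
#' @return `graph`, invisibly.
#' @export
write_pathway_graph <- function(graph, graphml = NULL, dot = NULL,
                                json = NULL) {
  stopifnot(inherits(graph, "pathway_graph"))
  ig <- as_igraph(graph)
  if (!is.null(graphml)) igraph::write_graph(ig, graphml, format = "graphml")
  if (!is.null(dot)) igraph::write_graph(ig, dot, format = "dot")
  if (!is.null(json)) {
    jsonlite::write_json(
      list(nodes = graph$nodes, edges = graph$edges),
      json, dataframe = "rows", auto_unbox = TRUE, digits = NA, pretty = TRUE
    )
  }
  invisible(graph)
}
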