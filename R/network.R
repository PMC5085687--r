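# Protein-interaction subnetwork analysis: induced subgraphs over a query gene
# set, connected components, connectivity summaries, and a hypergeometric
# gene-set overrepresentation test.

as_igraph <- function(graph) {
  igraph::graph_from_data_frame(
    as.data.frame(graph$edges, stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = data.frame(name = graph$nodes, stringsAsFactors = FALSE))
}

#' Induced subgraph over a query gene set
#'
#' Restricts the interaction graph to the query genes, keeping only edges with
#' both endpoints in the set. Query genes absent from the graph are allowed
#' and become isolated nodes.
#'
#' @param graph an [interaction_graph()].
#' @param genes character vector of query gene ids.
#' @return an `interaction_graph` whose node set is exactly `genes`.
#' @export
induced_subgraph <- function(graph, genes) {
  stopifnot(inherits(graph, "interaction_graph"))
  genes <- unique(as.character(genes))
  keep <- graph$edges[, 1] %in% genes & graph$edges[, 2] %in% genes
  interaction_graph(graph$edges[keep, , drop = FALSE], nodes = genes)
}

#' Connected components of an interaction graph
#'
#' Nodes with at least one edge are partitioned into standard undirected
#' connected components; degree-zero nodes are reported separately as
#' isolated. Components are ordered by size descending, ties broken by their
#' lexicographically smallest member; nodes within a component are sorted.
#'
#' @param graph an [interaction_graph()].
#' @return object of class `component_partition`: list with `components`
#'   (list of character vectors) and `isolated_nodes` (character vector).
#' @export
connected_components <- function(graph) {
  stopifnot(inherits(graph, "interaction_graph"))
  deg <- table(factor(as.vector(graph$edges), levels = graph$nodes))
  isolated <- sort(graph$nodes[deg == 0])
  comps <- list()
  if (nrow(graph$edges)) {
    sub <- interaction_graph(graph$edges)
    memb <- igraph::components(as_igraph(sub))$membership
    comps <- split(names(memb), memb)
    comps <- lapply(comps, function(x) sort(unname(x)))
    ord <- order(-lengths(comps), vapply(comps, `[[`, "", 1))
    comps <- unname(comps[ord])
  }
  structure(list(components = comps, isolated_nodes = isolated),
            class = "component_partition")
}

#' @export
print.component_partition <- function(x, ...) {
  cat(sprintf("component_partition: %d components (sizes %s), %d isolated\n",
              length(x$components),
              if (length(x$components))
                paste(lengths(x$components), collapse = ", ") else "-",
              length(x$isolated_nodes)))
  invisible(x)
}

#' Connectivity summary of a query gene set in an interaction graph
#'
#' Reports the funnel the subnetwork analysis is based on: how many query
#' genes there are, how many have at least one interaction among themselves,
#' and the size of the largest connected component of the induced subgraph.
#'
#' @param graph an [interaction_graph()].
#' @param genes query gene ids.
#' @return list with `n_query`, `n_with_interaction`,
#'   `largest_component_size`.
#' @export
connectivity_summary <- function(graph, genes) {
  sub <- induced_subgraph(graph, genes)
  parts <- connected_components(sub)
  list(n_query = length(sub$nodes),
       n_with_interaction = length(sub$nodes) - length(parts$isolated_nodes),
       largest_component_size =
         if (length(parts$components)) lengths(parts$components)[1] else 0L)
}

#' Hypergeometric gene-set overrepresentation test
#'
#' For each gene set, the overlap `k` between the query and the set (both
#' intersected with the universe) is tested against the upper-tail
#' hypergeometric probability `P(X >= k)` with the universe as background;
#' q-values are Benjamini-Hochberg over all tested sets. Rows passing
#' `p < alpha_p` and `q < alpha_q` are returned sorted by p ascending; the
#' full tested table is available as attribute `all_rows`.
#'
#' @param query character vector of query gene ids; must be a subset of
#'   `universe`.
#' @param universe character vector of background gene ids.
#' @param sets a [gene_set_collection()]. Sets empty after intersection with
#'   the universe are not tested.
#' @param alpha_p raw p-value cutoff (default 0.05).
#' @param alpha_q FDR cutoff (default 0.1).
#' @return data.frame of class `enrichment_result` with columns `set_name`,
#'   `overlap_count`, `set_size`, `query_size`, `universe_size`, `p`, `q`.
#' @export
hypergeometric_enrichment <- function(query, universe, sets,
                                      alpha_p = 0.05, alpha_q = 0.1) {
  stopifnot(inherits(sets, "gene_set_collection"))
  query <- unique(as.character(query))
  universe <- unique(as.character(universe))
  offenders <- setdiff(query, universe)
  if (length(offenders))
    stop("query gene(s) not in universe: ",
         paste(utils::head(offenders, 10), collapse = ", "), call. = FALSE)
  n_u <- length(universe)
  n_q <- length(query)
  rows <- lapply(names(sets$sets), function(nm) {
    s <- intersect(sets$sets[[nm]], universe)
    if (!length(s)) return(NULL)
    k <- length(intersect(s, query))
    p <- stats::phyper(k - 1, length(s), n_u - length(s), n_q,
                       lower.tail = FALSE)
    data.frame(set_name = nm, overlap_count = k, set_size = length(s),
               query_size = n_q, universe_size = n_u, p = p,
               stringsAsFactors = FALSE)
  })
  rows <- do.call(rbind, rows)
  if (is.null(rows))
    rows <- data.frame(set_name = character(), overlap_count = integer(),
                       set_size = integer(), query_size = integer(),
                       universe_size = integer(), p = numeric(),
                       stringsAsFactors = FALSE)
  rows$q <- bh_adjust(rows$p)
  keep <- !is.na(rows$p) & rows$p < alpha_p & rows$q < alpha_q
  out <- rows[keep, , drop = FALSE]
  out <- out[order(out$p, out$set_name), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("enrichment_result", "data.frame"),
            all_rows = rows, alpha_p = alpha_p, alpha_q = alpha_q)
}

#' Write connected components as TSV (node, component_index)
#'
#' Isolated nodes are written with component index 0.
#' @param parts a `component_partition`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_components <- function(parts, path) {
  rows <- data.frame(node = character(), component_index = integer(),
                     stringsAsFactors = FALSE)
  for (i in seq_along(parts$components))
    rows <- rbind(rows, data.frame(node = parts$components[[i]],
                                   component_index = i,
                                   stringsAsFactors = FALSE))
  if (length(parts$isolated_nodes))
    rows <- rbind(rows, data.frame(node = parts$isolated_nodes,
                                   component_index = 0L,
                                   stringsAsFactors = FALSE))
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
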