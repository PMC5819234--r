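#' Per-module interaction subnetworks
#'
#' For each named module, keeps the interaction edges with at least one
#' endpoint in the module. Non-member endpoints are retained with origin
#' "interaction_added" (a module gene has origin "module"), mirroring the
#' blue/red origin coloring of module network displays. Node degree is the
#' incident edge count within the module's graph, and the `top_n_labels`
#' highest-degree nodes are flagged for labeling in the report (degree ties
#' broken alphabetically). This display degree is distinct from the
#' adjacency-based intramodular connectivity of [hub_genes()]; both are
#' reported under different names.
#'
#' @param assignment Module assignment.
#' @param interactions data.frame with `gene_a`, `gene_b` (see
#'   [read_interactions()]).
#' @param top_n_labels Nodes flagged for labeling per module (default 10).
#' @return Named list per module: `nodes` (module, gene, origin, degree,
#'   labeled), `edges` (module, gene_a, gene_b). Modules without touching
#'   edges yield empty graphs (kept).
#' @export
module_interaction_graph <- function(assignment, interactions, top_n_labels = 10) {
  mods <- module_labels(assignment)
  out <- lapply(mods, function(m) {
    members <- names(assignment)[assignment == m]
    touch <- interactions$gene_a %in% members | interactions$gene_b %in% members
    edges <- interactions[touch, , drop = FALSE]
    if (nrow(edges) == 0L) {
      return(list(
        nodes = data.frame(module = character(), gene = character(),
                           origin = character(), degree = integer(),
                           labeled = logical(), stringsAsFactors = FALSE),
        edges = data.frame(module = character(), gene_a = character(),
                           gene_b = character(), stringsAsFactors = FALSE)))
    }
    g <- igraph::graph_from_data_frame(edges, directed = FALSE)
    deg <- igraph::degree(g)
    genes <- names(deg)
    ord <- order(-deg, genes)
    labeled <- logical(length(genes))
    labeled[utils::head(ord, top_n_labels)] <- TRUE
    nodes <- data.frame(
      module = m,
      gene = genes,
      origin = ifelse(genes %in% members, "module", "interaction_added"),
      degree = as.integer(deg),
      labeled = labeled,
      stringsAsFactors = FALSE, row.names = NULL)
    nodes <- nodes[order(-nodes$degree, nodes$gene), ]
    rownames(nodes) <- NULL
    list(nodes = nodes,
         edges = data.frame(module = m, gene_a = edges$gene_a,
                            gene_b = edges$gene_b, stringsAsFactors = FALSE,
                            row.names = NULL))
  })
  stats::setNames(out, mods)
}
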