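# Fast-greedy modularity on the bipartite graph treated as unipartite.

#' Fast-greedy modularity of an individual-resource network
#'
#' Treats the incidence matrix as an undirected bipartite graph (individuals
#' and food items are both nodes, links where cells are 1), and maximizes
#' Newman-Girvan modularity Q by greedy agglomeration of modules, returning
#' the partition with maximal Q along the merge path. The agglomeration is
#' igraph's deterministic fast-greedy implementation; the graph is not
#' projected to one mode, so modules may mix individuals and items.
#'
#' @param m an [incidence_matrix()] or plain 0/1 matrix with dimnames.
#' @return A list with `modularity` (Q), `membership` (named integer vector,
#'   module ids contiguous from 0, over individuals then items) and
#'   `n_modules`.
#' @export
fast_greedy_modularity <- function(m) {
  m <- prune_incidence(unclass(m))
  if (sum(m) < 1L) stop("graph with no edges: modularity undefined")
  if (is.null(rownames(m))) rownames(m) <- paste0("i", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- paste0("r", seq_len(ncol(m)))
  g <- igraph::graph_from_biadjacency_matrix(m)
  fg <- igraph::cluster_fast_greedy(g)
  memb <- igraph::membership(fg)
  ids <- as.integer(factor(memb, levels = unique(as.vector(memb)))) - 1L
  names(ids) <- names(memb)
  list(modularity = igraph::modularity(g, memb),
       membership = ids, n_modules = length(unique(ids)))
}
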