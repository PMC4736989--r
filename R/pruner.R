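#' Semantic graph pruning
#'
#' Removes from the target graph every vertex whose type is semantically
#' distant from all of the query's vertex types, then removes the edges
#' incident to removed vertices and finally any isolated vertices.  A target
#' vertex type survives iff its best score against the query's vertex types
#' reaches the threshold: `max over q in types(Q) of score(q, t) >= st`.
#'
#' Pruning shrinks the search space before a search.  In per-element mode it
#' is loss-free: no vertex of a surviving mapping can have been removed, so
#' search results on the pruned and unpruned graph are identical.  In
#' cumulative mode pruning may discard below-threshold elements that a
#' high-scoring mapping could have absorbed, which is why it defaults off
#' there (see [search_config()]).
#'
#' @param G target [typed_graph()] (not modified in place)
#' @param Q a [query_graph()]
#' @param matrices an [sdc_matrices()] object
#' @param st semantic threshold in \[0, 1\]
#' @return a new, pruned [typed_graph()]
#' @export
semantic_prune <- function(G, Q, matrices, st) {
  stopifnot(st >= 0, st <= 1)
  qtypes <- unique(Q$vertices$type)
  gtypes <- unique(G$vertices$type)
  best <- vapply(gtypes, function(t) {
    max(vapply(qtypes, function(q) score_pair(matrices, "vertex", q, t), numeric(1)))
  }, numeric(1))
  surviving_types <- gtypes[best >= st - 1e-12]
  keep <- G$vertices$id[G$vertices$type %in% surviving_types]
  pruned <- induced_subgraph_tg(G, keep)
  # drop vertices left (or already) isolated
  touched <- unique(c(pruned$edges$source, pruned$edges$target))
  induced_subgraph_tg(pruned, touched)
}
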