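#' Typed, directed, attributed multigraphs
#'
#' A `typed_graph` is the target network \eqn{G} mined by the search: a
#' directed multigraph whose vertices and edges carry a type drawn from a
#' finite vocabulary, plus arbitrary textual attributes.  Parallel edges and
#' self-loops are permitted; edge identifiers are unique.
#'
#' @param vertices data frame with columns `id` (unique, non-empty character)
#'   and `type` (character), and optionally `attrs`, a list column of named
#'   character vectors.
#' @param edges data frame with columns `id` (unique character), `source`,
#'   `target` (vertex ids), `type` (character), and optionally `attrs` as for
#'   vertices.
#' @return An object of class `typed_graph` with elements `vertices`,
#'   `edges`, `vertex_types`, `edge_types` (the observed type vocabularies).
#' @examples
#' g <- typed_graph(
#'   vertices = data.frame(id = c("a", "b"), type = c("Compound", "Target")),
#'   edges = data.frame(id = "e1", source = "a", target = "b", type = "binds_to")
#' )
#' n_vertices(g)
#' @export
typed_graph <- function(vertices = NULL, edges = NULL) {
  vertices <- normalise_element_frame(vertices, c("id", "type"), "vertex")
  edges <- normalise_element_frame(edges, c("id", "source", "target", "type"), "edge")
  g <- structure(
    list(
      vertices = vertices,
      edges = edges,
      vertex_types = sort(unique(vertices$type)),
      edge_types = sort(unique(edges$type))
    ),
    class = "typed_graph"
  )
  validate_typed_graph(g)
  g
}

normalise_element_frame <- function(df, cols, what) {
  if (is.null(df)) {
    df <- as.data.frame(stats::setNames(rep(list(character(0)), length(cols)), cols))
  }
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    stop(sprintf("%s table lacks column(s): %s", what, paste(missing, collapse = ", ")),
         call. = FALSE)
  }
  for (cl in cols) df[[cl]] <- as.character(df[[cl]])
  if (is.null(df$attrs)) {
    df$attrs <- rep(list(character(0)), nrow(df))
  } else {
    df$attrs <- lapply(df$attrs, function(a) {
      if (is.null(a) || length(a) == 0) return(character(0))
      stats::setNames(as.character(a), names(a))
    })
  }
  rownames(df) <- NULL
  df[c(cols, "attrs")]
}

validate_typed_graph <- function(g) {
  v <- g$vertices
  e <- g$edges
  if (anyNA(v$id) || any(!nzchar(v$id))) {
    stop("vertex ids must be non-empty", call. = FALSE)
  }
  if (anyDuplicated(v$id)) {
    stop("duplicate vertex id: ", v$id[duplicated(v$id)][1], call. = FALSE)
  }
  if (nrow(e) > 0) {
    if (anyDuplicated(e$id)) {
      stop("duplicate edge id: ", e$id[duplicated(e$id)][1], call. = FALSE)
    }
    known <- c(e$source, e$target) %in% v$id
    if (!all(known)) {
      bad <- c(e$source, e$target)[!known][1]
      stop("edge endpoint references absent vertex id: ", bad, call. = FALSE)
    }
  }
  invisible(g)
}

#' @export
print.typed_graph <- function(x, ...) {
  cat(sprintf(
    "typed_graph: %d vertices (%d types), %d edges (%d types)\n",
    nrow(x$vertices), length(x$vertex_types), nrow(x$edges), length(x$edge_types)
  ))
  invisible(x)
}

#' Number of vertices / edges
#' @param G a `typed_graph`
#' @return integer count
#' @export
n_vertices <- function(G) nrow(G$vertices)

#' @rdname n_vertices
#' @export
n_edges <- function(G) nrow(G$edges)

#' Vertex degree in a typed multigraph
#'
#' Degree counts edge multiplicity: parallel edges each count, and a
#' self-loop contributes 1 to the in-degree and 1 to the out-degree (so 2 to
#' the total).  This convention matters for the initial-candidate rule
#' \eqn{deg_G(v) \ge deg_Q(v)}, which must not under-count.
#'
#' @param G a `typed_graph`
#' @param v a vertex id present in `G`
#' @param direction one of `"in"`, `"out"`, `"total"`
#' @return non-negative integer
#' @export
degree <- function(G, v, direction = c("total", "in", "out")) {
  direction <- match.arg(direction)
  if (!v %in% G$vertices$id) stop("unknown vertex id: ", v, call. = FALSE)
  n_out <- sum(G$edges$source == v)
  n_in <- sum(G$edges$target == v)
  switch(direction, `in` = n_in, out = n_out, total = n_in + n_out)
}

#' All edges between two vertices
#'
#' Returns every edge `u -> v` and `v -> u` including parallel edges; when
#' `u == v` the self-loops on that vertex are returned once each.  This is the
#' primitive behind the closed-world check: a complete mapping is rejected if
#' any returned edge has no query counterpart.
#'
#' @param G a `typed_graph`
#' @param u,v vertex ids present in `G`
#' @return data frame of edge records (possibly zero rows)
#' @export
edges_between <- function(G, u, v) {
  for (x in unique(c(u, v))) {
    if (!x %in% G$vertices$id) stop("unknown vertex id: ", x, call. = FALSE)
  }
  e <- G$edges
  keep <- (e$source == u & e$target == v) | (e$source == v & e$target == u)
  res <- e[keep, , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Type-level summary (metagraph) of a typed graph
#'
#' Collapses the graph to its metagraph: one row per observed
#' (source type, edge type, target type) triple with the number of edges
#' realising it.  Counts sum to `n_edges(G)`.
#'
#' @param G a `typed_graph`
#' @return data frame with columns `source_type`, `edge_type`, `target_type`,
#'   `count`, ordered lexicographically
#' @export
metagraph <- function(G) {
  if (n_edges(G) == 0) {
    return(data.frame(
      source_type = character(0), edge_type = character(0),
      target_type = character(0), count = integer(0)
    ))
  }
  vt <- stats::setNames(G$vertices$type, G$vertices$id)
  key <- data.frame(
    source_type = unname(vt[G$edges$source]),
    edge_type = G$edges$type,
    target_type = unname(vt[G$edges$target])
  )
  agg <- stats::aggregate(list(count = rep(1L, nrow(key))), key, FUN = sum)
  agg <- agg[order(agg$source_type, agg$edge_type, agg$target_type), ]
  rownames(agg) <- NULL
  agg$count <- as.integer(agg$count)
  agg[c("source_type", "edge_type", "target_type", "count")]
}

#' Restrict a graph to a vertex subset
#'
#' Keeps the named vertices and every edge whose two endpoints survive.
#' Used by the semantic pruner; not exported surface for end users.
#' @noRd
induced_subgraph_tg <- function(G, keep_ids) {
  v <- G$vertices[G$vertices$id %in% keep_ids, , drop = FALSE]
  e <- G$edges[G$edges$source %in% keep_ids & G$edges$target %in% keep_ids, , drop = FALSE]
  rownames(v) <- NULL
  rownames(e) <- NULL
  structure(
    list(
      vertices = v, edges = e,
      vertex_types = sort(unique(v$type)),
      edge_types = sort(unique(e$type))
    ),
    class = "typed_graph"
  )
}
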