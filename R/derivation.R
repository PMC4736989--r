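#' Relevant interactions: known pairs absent from the mined network
#'
#' Given candidate drug-target pairs from external knowledge (typically a
#' newer release of an interaction database), retains exactly the pairs
#' whose drug and target both exist in the graph but are not yet connected
#' by an edge of the interaction type (in either direction).  These are the
#' pairs the mining can meaningfully rediscover, and the reference set that
#' query scoring is computed against.
#'
#' @param G target [typed_graph()]
#' @param candidate_pairs data frame with columns `drug`, `target`
#' @param interaction_edge_type edge type name (e.g. `"binds_to"`)
#' @param label optional label for the returned set
#' @return an object of class `reference_set`: list with `pairs` (data frame
#'   `drug`, `target`, unique rows) and `label`
#' @export
relevant_interactions <- function(G, candidate_pairs, interaction_edge_type,
                                  label = "reference") {
  p <- as.data.frame(candidate_pairs, stringsAsFactors = FALSE)
  stopifnot(all(c("drug", "target") %in% names(p)))
  p$drug <- as.character(p$drug)
  p$target <- as.character(p$target)
  p <- p[!duplicated(paste(p$drug, p$target)), , drop = FALSE]
  present <- p$drug %in% G$vertices$id & p$target %in% G$vertices$id
  p <- p[present, , drop = FALSE]
  if (nrow(p) > 0) {
    e <- G$edges[G$edges$type == interaction_edge_type, , drop = FALSE]
    linked_key <- c(paste(e$source, e$target), paste(e$target, e$source))
    p <- p[!(paste(p$drug, p$target) %in% linked_key), , drop = FALSE]
  }
  rownames(p) <- NULL
  structure(list(pairs = p[c("drug", "target")], label = label),
            class = "reference_set")
}

#' @export
print.reference_set <- function(x, ...) {
  cat(sprintf("reference_set '%s': %d pair(s)\n", x$label, nrow(x$pairs)))
  invisible(x)
}

#' Shortest semantic path between two vertices
#'
#' A minimum-hop path on the undirected view of the graph; among equal-length
#' paths the lexicographically smallest vertex-id sequence is chosen, and
#' between each consecutive vertex pair the smallest-id connecting edge.
#' Edge directions and types are reported as stored in the graph.
#'
#' @param G a [typed_graph()]
#' @param a,b vertex ids
#' @return an object of class `semantic_path`: list with `vertex_ids`,
#'   `vertex_types` and `edges` (data frame of the traversed edge records in
#'   path order, with original orientation)
#' @export
shortest_semantic_path <- function(G, a, b) {
  idx <- build_graph_index(G)
  ia <- vertex_index_of(idx, a)
  ib <- vertex_index_of(idx, b)
  if (is.na(ia)) stop("unknown vertex id: ", a, call. = FALSE)
  if (is.na(ib)) stop("unknown vertex id: ", b, call. = FALSE)

  # BFS distances to b on the undirected view
  dist <- rep(NA_integer_, idx$n)
  dist[ib] <- 0L
  frontier <- ib
  while (length(frontier) > 0) {
    nxt <- unique(c(unlist(idx$nb_out[frontier], use.names = FALSE),
                    unlist(idx$nb_in[frontier], use.names = FALSE)))
    nxt <- nxt[is.na(dist[nxt])]
    dist[nxt] <- dist[frontier[1]] + 1L
    frontier <- nxt
  }
  if (is.na(dist[ia])) {
    stop("no path between '", a, "' and '", b, "'", call. = FALSE)
  }

  # greedy descent: smallest-id neighbour one hop closer to b
  path <- ia
  cur <- ia
  while (cur != ib) {
    nbs <- unique(c(idx$nb_out[[cur]], idx$nb_in[[cur]]))
    nbs <- nbs[!is.na(dist[nbs]) & dist[nbs] == dist[cur] - 1L]
    cur <- nbs[order(idx$vid[nbs])][1]
    path <- c(path, cur)
  }

  edge_rows <- integer(0)
  for (i in seq_len(length(path) - 1)) {
    u <- path[i]; v <- path[i + 1]
    cand <- c(pair_edge_idx(idx, u, v), pair_edge_idx(idx, v, u))
    edge_rows <- c(edge_rows, cand[order(idx$eid[cand])][1])
  }
  structure(
    list(
      vertex_ids = idx$vid[path],
      vertex_types = idx$vtype[path],
      edges = G$edges[edge_rows, , drop = FALSE]
    ),
    class = "semantic_path"
  )
}

#' Convert a semantic path into a query subgraph
#'
#' Every vertex on the path becomes a typed query role (identities are not
#' pinned: the query is type-level) and every path edge a query edge with
#' its original type and direction.  The inference annotation connects the
#' first role (the drug end) to the last role (the target end) with the
#' supplied edge type.
#'
#' @param path a `semantic_path` from [shortest_semantic_path()]
#' @param inferred_edge_type edge type of the inferred relation
#' @return a [query_graph()]
#' @export
path_to_query <- function(path, inferred_edge_type) {
  nv <- length(path$vertex_ids)
  if (nv < 2) stop("path must contain at least one edge", call. = FALSE)
  roles <- sprintf("r%d", seq_len(nv))
  role_of <- stats::setNames(roles, path$vertex_ids)
  edges <- data.frame(
    source = unname(role_of[path$edges$source]),
    target = unname(role_of[path$edges$target]),
    type = path$edges$type
  )
  query_graph(
    vertices = data.frame(role = roles, type = path$vertex_types),
    edges = edges,
    inference = list(source = roles[1], target = roles[nv],
                     type = inferred_edge_type)
  )
}

# Canonical string form of a query under typed-digraph isomorphism
# (including the inference annotation): minimum key over all orderings that
# permute roles within same-type blocks.
canonical_query_key <- function(Q) {
  v <- Q$vertices[order(Q$vertices$type, Q$vertices$role), , drop = FALSE]
  types <- v$type
  blocks <- split(seq_len(nrow(v)), types)

  block_perms <- lapply(blocks, function(ix) {
    lapply(small_perms(length(ix)), function(p) ix[p])
  })

  inf <- Q$inference
  best <- NULL
  try_order <- function(bi, chosen) {
    if (bi > length(block_perms)) {
      ord <- unlist(chosen)           # row indices of v in canonical position order
      pos <- integer(nrow(v))
      pos[ord] <- seq_along(ord)
      role_pos <- stats::setNames(pos, v$role)
      e <- sprintf("%d>%d:%s", role_pos[Q$edges$source],
                   role_pos[Q$edges$target], Q$edges$type)
      key <- paste(
        paste(types[ord], collapse = ","),
        paste(sort(e), collapse = ","),
        if (is.null(inf)) "" else
          sprintf("%d>%d:%s", role_pos[inf$source], role_pos[inf$target], inf$type),
        sep = ";"
      )
      if (is.null(best) || key < best) best <<- key
      return(invisible(NULL))
    }
    for (p in block_perms[[bi]]) try_order(bi + 1, c(chosen, list(p)))
  }
  try_order(1, list())
  best
}

#' Deduplicate derived queries by typed isomorphism
#'
#' Groups queries by typed-digraph isomorphism (topology, vertex and edge
#' types, direction, and the inference annotation) and returns one canonical
#' representative per class together with its multiplicity.  Queries larger
#' than `max_vertices` are discarded with a warning.  The canonical form is
#' computed by exhaustive type-partitioned permutation, feasible at the
#' query sizes used here (at most 9 roles).
#'
#' @param queries list of [query_graph()] objects
#' @param max_vertices maximum role count retained (default 9)
#' @return list of entries `list(query = , multiplicity = )`
#' @export
dedup_queries <- function(queries, max_vertices = 9) {
  sizes <- vapply(queries, function(q) nrow(q$vertices), integer(1))
  if (any(sizes > max_vertices)) {
    warning(sum(sizes > max_vertices), " quer(ies) larger than ",
            max_vertices, " vertices discarded", call. = FALSE)
    queries <- queries[sizes <= max_vertices]
  }
  if (length(queries) == 0) return(list())
  keys <- vapply(queries, canonical_query_key, character(1))
  out <- list()
  for (kk in unique(keys)) {
    sel <- which(keys == kk)
    out[[length(out) + 1L]] <- list(query = queries[[sel[1]]],
                                    multiplicity = length(sel))
  }
  out
}

#' Derive a deduplicated query set from known drug-target pairs
#'
#' The full derivation pipeline: keep the relevant pairs (both endpoints in
#' the graph, no existing interaction edge), extract the shortest semantic
#' path for each, convert each path into a type-level query inferring the
#' interaction edge, and deduplicate by typed isomorphism.  Pairs with no
#' connecting path are skipped (and reported via `attr(, "skipped")`).
#'
#' @param G target [typed_graph()]
#' @param pairs data frame with columns `drug`, `target`
#' @param interaction_edge_type edge type of the interaction to infer
#' @param max_vertices maximum query size retained
#' @return as [dedup_queries()], with attribute `skipped` (data frame of
#'   unreachable pairs)
#' @export
derive_queries <- function(G, pairs, interaction_edge_type = "binds_to",
                           max_vertices = 9) {
  rel <- relevant_interactions(G, pairs, interaction_edge_type)
  queries <- list()
  skipped <- list()
  for (i in seq_len(nrow(rel$pairs))) {
    d <- rel$pairs$drug[i]; t <- rel$pairs$target[i]
    p <- tryCatch(shortest_semantic_path(G, d, t), error = function(e) NULL)
    if (is.null(p)) {
      skipped[[length(skipped) + 1L]] <- rel$pairs[i, ]
      next
    }
    queries[[length(queries) + 1L]] <- path_to_query(p, interaction_edge_type)
  }
  out <- dedup_queries(queries, max_vertices)
  attr(out, "skipped") <- if (length(skipped)) do.call(rbind, skipped) else
    data.frame(drug = character(0), target = character(0))
  out
}
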