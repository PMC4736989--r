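#' Semantic query subgraphs
#'
#' A `query_graph` is the pattern searched for in the target network: a small
#' connected typed directed multigraph over abstract *roles*, optionally
#' carrying an inference annotation `(source role, target role, edge type)`.
#' Each embedding of the query then infers an edge of that type between the
#' images of the two roles (e.g. a `binds_to` relation between a compound and
#' a target).  The inferred edge type need not occur among the structural
#' edges of the query.
#'
#' @param vertices data frame with columns `role` (unique ids) and `type`
#' @param edges data frame with columns `source`, `target`, `type` and
#'   optionally `id` (generated as `qe1`, `qe2`, ... when absent)
#' @param inference `NULL`, or a list/vector with elements `source`, `target`,
#'   `type` naming existing roles and the inferred edge type
#' @return an object of class `query_graph`
#' @examples
#' q <- query_graph(
#'   vertices = data.frame(role = c("c1", "c2", "t1"),
#'                         type = c("Compound", "Compound", "Target")),
#'   edges = data.frame(source = c("c1", "c2"), target = c("c2", "t1"),
#'                      type = c("similar_to", "binds_to")),
#'   inference = list(source = "c1", target = "t1", type = "binds_to")
#' )
#' @export
query_graph <- function(vertices, edges, inference = NULL) {
  vertices <- as.data.frame(vertices, stringsAsFactors = FALSE)
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  stopifnot(all(c("role", "type") %in% names(vertices)))
  vertices$role <- as.character(vertices$role)
  vertices$type <- as.character(vertices$type)
  if (nrow(edges) == 0) {
    edges <- data.frame(id = character(0), source = character(0),
                        target = character(0), type = character(0))
  } else {
    stopifnot(all(c("source", "target", "type") %in% names(edges)))
    if (is.null(edges$id)) edges$id <- paste0("qe", seq_len(nrow(edges)))
    edges <- data.frame(id = as.character(edges$id),
                        source = as.character(edges$source),
                        target = as.character(edges$target),
                        type = as.character(edges$type))
  }
  if (!is.null(inference)) {
    inference <- as.list(inference)[c("source", "target", "type")]
    if (any(vapply(inference, is.null, logical(1)))) {
      stop("inference must supply source, target and type", call. = FALSE)
    }
    inference <- lapply(inference, as.character)
  }
  q <- structure(
    list(vertices = vertices, edges = edges, inference = inference),
    class = "query_graph"
  )
  validate_query_graph(q)
  q
}

validate_query_graph <- function(q) {
  v <- q$vertices
  e <- q$edges
  if (nrow(v) < 2) stop("a query needs at least 2 roles", call. = FALSE)
  if (anyDuplicated(v$role)) {
    stop("duplicate role id: ", v$role[duplicated(v$role)][1], call. = FALSE)
  }
  if (nrow(e) > 0) {
    if (anyDuplicated(e$id)) stop("duplicate query edge id", call. = FALSE)
    bad <- setdiff(c(e$source, e$target), v$role)
    if (length(bad) > 0) stop("query edge references unknown role: ", bad[1], call. = FALSE)
  }
  if (!query_is_connected(q)) {
    stop("query must be connected in the undirected view", call. = FALSE)
  }
  if (!is.null(q$inference)) {
    bad <- setdiff(c(q$inference$source, q$inference$target), v$role)
    if (length(bad) > 0) {
      stop("inference annotation references unknown role: ", bad[1], call. = FALSE)
    }
  }
  invisible(q)
}

#' @export
print.query_graph <- function(x, ...) {
  cat(sprintf("query_graph: %d roles, %d edges%s\n",
              nrow(x$vertices), nrow(x$edges),
              if (is.null(x$inference)) "" else
                sprintf(", infers %s -[%s]-> %s", x$inference$source,
                        x$inference$type, x$inference$target)))
  invisible(x)
}

# Undirected adjacency over roles (simple view: unique neighbour sets).
query_adjacency <- function(q) {
  roles <- q$vertices$role
  adj <- stats::setNames(rep(list(character(0)), length(roles)), roles)
  for (i in seq_len(nrow(q$edges))) {
    s <- q$edges$source[i]; t <- q$edges$target[i]
    if (s != t) {
      adj[[s]] <- union(adj[[s]], t)
      adj[[t]] <- union(adj[[t]], s)
    }
  }
  adj
}

query_is_connected <- function(q) {
  roles <- q$vertices$role
  if (length(roles) <= 1) return(TRUE)
  adj <- query_adjacency(q)
  seen <- stats::setNames(rep(FALSE, length(roles)), roles)
  frontier <- roles[1]
  seen[frontier] <- TRUE
  while (length(frontier) > 0) {
    nxt <- setdiff(unique(unlist(adj[frontier], use.names = FALSE)),
                   names(seen)[seen])
    seen[nxt] <- TRUE
    frontier <- nxt
  }
  all(seen)
}

# Total degree of each role, counting multiplicity; a self-loop adds 2.
query_degrees <- function(q) {
  roles <- q$vertices$role
  deg <- stats::setNames(integer(length(roles)), roles)
  if (nrow(q$edges) > 0) {
    tab <- table(factor(c(q$edges$source, q$edges$target), levels = roles))
    deg[names(tab)] <- as.integer(tab)
  }
  deg
}

# Hop distances between all role pairs on the undirected simple view.
query_distances <- function(q) {
  roles <- q$vertices$role
  n <- length(roles)
  adj <- query_adjacency(q)
  d <- matrix(Inf, n, n, dimnames = list(roles, roles))
  diag(d) <- 0
  for (r in roles) {
    frontier <- r
    dist <- 0
    while (length(frontier) > 0) {
      dist <- dist + 1
      nxt <- setdiff(unique(unlist(adj[frontier], use.names = FALSE)),
                     roles[is.finite(d[r, ])])
      d[r, nxt] <- dist
      frontier <- nxt
    }
  }
  d
}

# Lexicographically smallest shortest role-id path a -> b (undirected view).
query_shortest_path <- function(q, a, b) {
  d <- query_distances(q)
  if (!is.finite(d[a, b])) stop("roles are not connected", call. = FALSE)
  adj <- query_adjacency(q)
  path <- a
  cur <- a
  while (cur != b) {
    cand <- adj[[cur]][d[adj[[cur]], b] == d[cur, b] - 1]
    cur <- sort(cand)[1]
    path <- c(path, cur)
  }
  path
}

#' Read a query subgraph from JSON
#'
#' The JSON layout is
#' `{"vertices": [{"role": "c1", "type": "Compound"}, ...],`
#' `"edges": [{"source": "c1", "target": "c2", "type": "similar_to"}, ...],`
#' `"inference": {"source": "c1", "target": "t1", "type": "binds_to"}}`
#' with `inference` optional.
#'
#' @param path JSON file
#' @return a [query_graph()]
#' @export
load_query <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  j <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  inference <- j$inference
  if (!is.null(inference)) inference <- as.list(inference)
  query_graph(j$vertices, if (is.null(j$edges)) data.frame() else j$edges, inference)
}

#' Write a query subgraph to JSON
#' @param Q a [query_graph()]
#' @param path output file
#' @export
save_query <- function(Q, path) {
  obj <- list(
    vertices = Q$vertices[c("role", "type")],
    edges = Q$edges[c("source", "target", "type", "id")]
  )
  if (!is.null(Q$inference)) obj$inference <- Q$inference
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
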