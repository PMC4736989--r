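# Internal integer-indexed view of a typed_graph, built once per search.
# Everything downstream works on integer vertex/edge indices; the id <-> index
# translation happens only at the API boundary.

build_graph_index <- function(G) {
  vid <- G$vertices$id
  n <- length(vid)
  id2idx <- new.env(parent = emptyenv(), size = max(n, 29L))
  for (i in seq_len(n)) assign(vid[i], i, envir = id2idx)

  esrc <- match(G$edges$source, vid)
  etgt <- match(G$edges$target, vid)
  m <- length(esrc)

  fac <- function(x) factor(x, levels = seq_len(n))
  out_e <- split(seq_len(m), fac(esrc))
  in_e <- split(seq_len(m), fac(etgt))

  deg_out <- tabulate(esrc, nbins = n)
  deg_in <- tabulate(etgt, nbins = n)

  # Directed pair lookup "s|t" -> edge indices (self-loops under "v|v").
  pair_env <- new.env(parent = emptyenv(), size = max(m, 29L))
  if (m > 0) {
    key <- paste(esrc, etgt, sep = "|")
    grp <- split(seq_len(m), key)
    for (k in names(grp)) assign(k, grp[[k]], envir = pair_env)
  }

  # Unique neighbour vertex indices per vertex (both directions, no self).
  nb_out <- lapply(out_e, function(es) etgt[es])
  nb_in <- lapply(in_e, function(es) esrc[es])

  list(
    n = n, m = m,
    vid = vid, vtype = G$vertices$type,
    esrc = esrc, etgt = etgt,
    etype = G$edges$type, eid = G$edges$id,
    out_e = out_e, in_e = in_e,
    nb_out = nb_out, nb_in = nb_in,
    deg_total = deg_in + deg_out,
    id2idx = id2idx, pair_env = pair_env
  )
}

pair_edge_idx <- function(idx, s, t) {
  k <- paste0(s, "|", t)
  if (exists(k, envir = idx$pair_env, inherits = FALSE)) {
    get(k, envir = idx$pair_env, inherits = FALSE)
  } else integer(0)
}

vertex_index_of <- function(idx, id) {
  if (exists(id, envir = idx$id2idx, inherits = FALSE)) {
    get(id, envir = idx$id2idx, inherits = FALSE)
  } else NA_integer_
}

# Internal integer-indexed view of a query_graph.
build_query_index <- function(Q) {
  roles <- Q$vertices$role
  k <- length(roles)
  qsrc <- match(Q$edges$source, roles)
  qtgt <- match(Q$edges$target, roles)
  deg <- tabulate(qsrc, nbins = k) + tabulate(qtgt, nbins = k)

  # per ordered role pair (i, j): indices of parallel query edges i -> j
  pair_key <- paste(qsrc, qtgt, sep = "|")
  pair_edges <- split(seq_along(qsrc), pair_key)

  # undirected simple adjacency over role indices
  adj <- rep(list(integer(0)), k)
  for (e in seq_along(qsrc)) {
    i <- qsrc[e]; j <- qtgt[e]
    if (i != j) {
      adj[[i]] <- union(adj[[i]], j)
      adj[[j]] <- union(adj[[j]], i)
    }
  }
  list(
    k = k, roles = roles, rtype = Q$vertices$type,
    qsrc = qsrc, qtgt = qtgt, qetype = Q$edges$type, qeid = Q$edges$id,
    deg = deg, adj = adj, pair_edges = pair_edges
  )
}
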