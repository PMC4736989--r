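#' Specification of a random semantic graph
#'
#' Bundles per-type vertex counts and per-metagraph-triple edge counts.  The
#' random generator realises both exactly, which by construction maintains
#' the per-type average in- and out-degrees the spec encodes.
#'
#' @param vertex_counts named integer vector: vertex type -> count
#' @param triple_rates data frame with columns `source_type`, `edge_type`,
#'   `target_type`, `count`
#' @param seed integer seed
#' @return an object of class `synthetic_spec`
#' @export
synthetic_spec <- function(vertex_counts, triple_rates, seed = 1L) {
  vertex_counts <- vapply(vertex_counts, function(x) as.integer(x), integer(1))
  if (any(vertex_counts < 0)) stop("vertex counts must be >= 0", call. = FALSE)
  tr <- as.data.frame(triple_rates, stringsAsFactors = FALSE)
  if (nrow(tr) > 0) {
    stopifnot(all(c("source_type", "edge_type", "target_type", "count") %in% names(tr)))
    undeclared <- setdiff(unique(c(tr$source_type, tr$target_type)),
                          names(vertex_counts))
    if (length(undeclared) > 0) {
      stop("triple references undeclared vertex type: ", undeclared[1], call. = FALSE)
    }
    tr$count <- as.integer(tr$count)
  } else {
    tr <- data.frame(source_type = character(0), edge_type = character(0),
                     target_type = character(0), count = integer(0))
  }
  structure(list(vertex_counts = vertex_counts, triple_rates = tr,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' @export
print.synthetic_spec <- function(x, ...) {
  cat(sprintf("synthetic_spec: %d vertices over %d types, %d edges over %d triples\n",
              sum(x$vertex_counts), length(x$vertex_counts),
              sum(x$triple_rates$count), nrow(x$triple_rates)))
  invisible(x)
}

#' Read the generating spec off an existing graph
#'
#' Returns the spec whose random realisations replicate the graph's
#' semantic and topological profile: identical per-type vertex counts and
#' per-triple edge counts (the metagraph counts), hence identical per-type
#' average in/out degrees.
#'
#' @param G a [typed_graph()]
#' @param seed seed stored in the returned spec
#' @return a [synthetic_spec()]
#' @export
spec_from_graph <- function(G, seed = 1L) {
  counts <- table(G$vertices$type)
  synthetic_spec(stats::setNames(as.integer(counts), names(counts)),
                 metagraph(G), seed = seed)
}

#' Generate a random semantic graph
#'
#' Realises a [synthetic_spec()] exactly: the stated number of vertices per
#' type, and for each metagraph triple the stated number of edges whose
#' endpoints are drawn uniformly at random from the corresponding type
#' populations.  Self-loops are rejected and resampled; parallel edges are
#' allowed.  Fully reproducible from the seed.
#'
#' @param spec a [synthetic_spec()]
#' @param seed seed (defaults to the spec's)
#' @return a [typed_graph()]
#' @export
random_graph <- function(spec, seed = spec$seed) {
  stopifnot(inherits(spec, "synthetic_spec"))
  types <- names(spec$vertex_counts)
  ids_by_type <- lapply(types, function(t) {
    n <- spec$vertex_counts[[t]]
    if (n == 0) character(0) else sprintf("%s_%d", t, seq_len(n))
  })
  names(ids_by_type) <- types
  vertices <- data.frame(
    id = unlist(ids_by_type, use.names = FALSE),
    type = rep(types, times = lengths(ids_by_type))
  )
  tr <- spec$triple_rates
  withr::with_seed(seed, {
    srcs <- character(0); tgts <- character(0); etys <- character(0)
    for (i in seq_len(nrow(tr))) {
      ns <- tr$count[i]
      if (ns == 0) next
      sp <- ids_by_type[[tr$source_type[i]]]
      tp <- ids_by_type[[tr$target_type[i]]]
      if (length(sp) == 0 || length(tp) == 0) {
        stop(sprintf("triple (%s, %s, %s) references an empty type population",
                     tr$source_type[i], tr$edge_type[i], tr$target_type[i]),
             call. = FALSE)
      }
      if (identical(tr$source_type[i], tr$target_type[i]) && length(sp) < 2) {
        stop("cannot draw loop-free edges within a single-vertex type", call. = FALSE)
      }
      s <- sample(sp, ns, replace = TRUE)
      t <- sample(tp, ns, replace = TRUE)
      bad <- which(s == t)
      while (length(bad) > 0) {
        t[bad] <- sample(tp, length(bad), replace = TRUE)
        bad <- bad[s[bad] == t[bad]]
      }
      srcs <- c(srcs, s); tgts <- c(tgts, t)
      etys <- c(etys, rep(tr$edge_type[i], ns))
    }
    edges <- data.frame(
      id = if (length(srcs)) sprintf("e%d", seq_along(srcs)) else character(0),
      source = srcs, target = tgts, type = etys
    )
    typed_graph(vertices, edges)
  })
}

#' Generate a random connected query
#'
#' Builds a random spanning tree over `n_vertices` roles (each new role
#' attaches to a uniformly chosen earlier role, with random direction) plus
#' `extra_edges` additional random non-loop edges; parallel extra edges may
#' occur.  Types are taken from `vertex_types` in order when exactly
#' `n_vertices` are supplied, otherwise drawn uniformly; edge types are
#' drawn uniformly from `edge_types`.  When a `metagraph` (as returned by
#' [metagraph()]) is supplied, growth is type-consistent instead: each new
#' role attaches via a triple compatible with its neighbour's type, so the
#' query is realisable in graphs sharing that metagraph.  When all vertex
#' types are pairwise distinct the query is rigid (trivial type-respecting
#' automorphism group).
#'
#' @param n_vertices number of roles, between 3 and 9
#' @param vertex_types,edge_types type vocabularies (see above)
#' @param extra_edges number of non-tree edges (>= 0)
#' @param seed integer seed
#' @param metagraph optional data frame of allowed (source, edge, target)
#'   type triples
#' @return a [query_graph()] with roles `v1 < v2 < ...`
#' @export
random_query <- function(n_vertices, vertex_types = NULL, edge_types = NULL,
                         extra_edges = 0, seed = 1L, metagraph = NULL) {
  if (n_vertices < 3 || n_vertices > 9) {
    stop("n_vertices must be between 3 and 9", call. = FALSE)
  }
  if (extra_edges < 0) stop("impossible edge count: extra_edges < 0", call. = FALSE)
  withr::with_seed(seed, {
    roles <- sprintf("v%d", seq_len(n_vertices))
    if (is.null(metagraph)) {
      if (is.null(vertex_types) || is.null(edge_types)) {
        stop("supply vertex_types and edge_types, or a metagraph", call. = FALSE)
      }
      types <- if (length(vertex_types) == n_vertices) as.character(vertex_types)
               else sample(vertex_types, n_vertices, replace = TRUE)
      src <- character(0); tgt <- character(0); ety <- character(0)
      for (i in 2:n_vertices) {
        j <- if (i == 2) 1L else sample.int(i - 1L, 1)
        if (stats::runif(1) < 0.5) {
          src <- c(src, roles[j]); tgt <- c(tgt, roles[i])
        } else {
          src <- c(src, roles[i]); tgt <- c(tgt, roles[j])
        }
        ety <- c(ety, sample(edge_types, 1))
      }
      for (x in seq_len(extra_edges)) {
        pr <- sample.int(n_vertices, 2, replace = FALSE)
        src <- c(src, roles[pr[1]]); tgt <- c(tgt, roles[pr[2]])
        ety <- c(ety, sample(edge_types, 1))
      }
    } else {
      mg <- as.data.frame(metagraph, stringsAsFactors = FALSE)
      if (nrow(mg) == 0) stop("metagraph has no triples", call. = FALSE)
      types <- character(n_vertices)
      types[1] <- sample(unique(c(mg$source_type, mg$target_type)), 1)
      src <- character(0); tgt <- character(0); ety <- character(0)
      for (i in 2:n_vertices) {
        repeat {
          j <- if (i == 2) 1L else sample.int(i - 1L, 1)
          compat <- mg[mg$source_type == types[j] | mg$target_type == types[j], ,
                       drop = FALSE]
          if (nrow(compat) > 0) break
        }
        tri <- compat[sample.int(nrow(compat), 1), ]
        as_source <- tri$source_type == types[j]
        if (as_source && tri$target_type == types[j] && stats::runif(1) < 0.5) {
          as_source <- FALSE
        }
        if (as_source) {
          types[i] <- tri$target_type
          src <- c(src, roles[j]); tgt <- c(tgt, roles[i])
        } else {
          types[i] <- tri$source_type
          src <- c(src, roles[i]); tgt <- c(tgt, roles[j])
        }
        ety <- c(ety, tri$edge_type)
      }
      added <- 0L
      attempts <- 0L
      while (added < extra_edges && attempts < 100L * (extra_edges + 1L)) {
        attempts <- attempts + 1L
        pr <- sample.int(n_vertices, 2, replace = FALSE)
        compat <- mg[mg$source_type == types[pr[1]] & mg$target_type == types[pr[2]], ,
                     drop = FALSE]
        if (nrow(compat) == 0) next
        tri <- compat[sample.int(nrow(compat), 1), ]
        src <- c(src, roles[pr[1]]); tgt <- c(tgt, roles[pr[2]])
        ety <- c(ety, tri$edge_type)
        added <- added + 1L
      }
    }
    query_graph(
      vertices = data.frame(role = roles, type = types),
      edges = data.frame(source = src, target = tgt, type = ety)
    )
  })
}

#' Test whether a query is rigid
#'
#' A query is rigid when its only type-respecting automorphism (preserving
#' edge multiset with types and direction, and the inference annotation) is
#' the identity.  Planted copies of a rigid query each contribute exactly
#' one mapping.  Checked by exhaustive permutation over same-type role
#' blocks.
#'
#' @param Q a [query_graph()]
#' @return logical flag
#' @export
query_is_rigid <- function(Q) {
  roles <- Q$vertices$role
  typ <- stats::setNames(Q$vertices$type, roles)
  blocks <- split(roles, typ[roles])
  edge_multiset <- function(perm) {
    sort(paste(perm[Q$edges$source], perm[Q$edges$target], Q$edges$type))
  }
  ref <- edge_multiset(stats::setNames(roles, roles))
  inf_key <- function(perm) {
    if (is.null(Q$inference)) "" else
      paste(perm[Q$inference$source], perm[Q$inference$target], Q$inference$type)
  }
  ref_inf <- inf_key(stats::setNames(roles, roles))

  found_nontrivial <- FALSE
  rec <- function(bi, perm) {
    if (found_nontrivial) return(invisible(NULL))
    if (bi > length(blocks)) {
      if (all(perm[roles] == roles)) return(invisible(NULL))
      if (identical(edge_multiset(perm), ref) &&
          identical(inf_key(perm), ref_inf)) {
        found_nontrivial <<- TRUE
      }
      return(invisible(NULL))
    }
    b <- blocks[[bi]]
    for (p in small_perms(length(b))) {
      perm[b] <- b[p]
      rec(bi + 1, perm)
    }
  }
  rec(1, stats::setNames(roles, roles))
  !found_nontrivial
}

#' Plant disjoint copies of a query into a graph
#'
#' Adds `k` copies of the query as vertex-disjoint components built from
#' fresh vertices carrying the query's types and exactly its edges, with no
#' edges to pre-existing vertices.  For a rigid query, searching the spiked
#' graph therefore returns exactly `k` more mappings than the unspiked one.
#'
#' @param G a [typed_graph()]
#' @param Q a connected [query_graph()]
#' @param k number of copies (>= 0)
#' @param seed kept for interface symmetry; planting is deterministic
#' @return a new [typed_graph()] with the planted components
#' @export
plant_instances <- function(G, Q, k, seed = 1L) {
  if (k == 0) return(G)
  roles <- Q$vertices$role
  new_v <- do.call(rbind, lapply(seq_len(k), function(i) {
    data.frame(id = sprintf("plant%d_%s", i, roles), type = Q$vertices$type)
  }))
  new_e <- do.call(rbind, lapply(seq_len(k), function(i) {
    data.frame(
      id = sprintf("plant%d_%s", i, Q$edges$id),
      source = sprintf("plant%d_%s", i, Q$edges$source),
      target = sprintf("plant%d_%s", i, Q$edges$target),
      type = Q$edges$type
    )
  }))
  v <- rbind(G$vertices[c("id", "type")], new_v)
  v$attrs <- c(G$vertices$attrs, rep(list(character(0)), nrow(new_v)))
  e <- rbind(G$edges[c("id", "source", "target", "type")], new_e)
  e$attrs <- c(G$edges$attrs, rep(list(character(0)), nrow(new_e)))
  typed_graph(v, e)
}

#' A scaled-down drug-discovery network spec
#'
#' The default study conditions of this package's synthetic evaluation: four
#' core concept classes (Compound, Target, Protein, Disease in proportions
#' 0.35 / 0.20 / 0.30 / 0.15) connected by eight metagraph triples
#' (compound similarity, compound-target binding, indications, target
#' similarity, disease involvement, target-protein identity, protein
#' sequence similarity and a disease hierarchy) with an average total degree
#' of about 3.4.  Relative type connectivity follows an integrated
#' drug-discovery network; absolute densities are scaled to desk size.
#'
#' @param n_vertices total vertex count (distributed over the four classes)
#' @param seed stored seed
#' @return a [synthetic_spec()]
#' @export
drug_network_spec <- function(n_vertices = 10000, seed = 1L) {
  nC <- round(0.35 * n_vertices)
  nT <- round(0.20 * n_vertices)
  nP <- round(0.30 * n_vertices)
  nD <- n_vertices - nC - nT - nP
  synthetic_spec(
    vertex_counts = c(Compound = nC, Target = nT, Protein = nP, Disease = nD),
    triple_rates = data.frame(
      source_type = c("Compound", "Compound", "Compound", "Target", "Target",
                      "Target", "Protein", "Disease"),
      edge_type = c("similar_to", "binds_to", "may_treat", "similar_to",
                    "involved_in", "is_a", "has_similar_sequence", "is_a"),
      target_type = c("Compound", "Target", "Disease", "Target", "Disease",
                      "Protein", "Protein", "Disease"),
      count = c(round(0.8 * nC), round(1.2 * nC), round(0.6 * nC),
                round(0.6 * nT), round(0.8 * nT), nT,
                round(0.8 * nP), round(0.5 * nD))
    ),
    seed = seed
  )
}

#' The chlorpromazine guilt-by-association fixture
#'
#' A six-vertex network capturing a classic repositioning situation: the
#' antipsychotic chlorpromazine binds three annotated targets, none of which
#' explains its antihistaminic effect; it is structurally similar to
#' trimeprazine, which binds the Histamine H1 receptor.  The accompanying
#' triad query (compound similar to a compound that binds a target) infers
#' the missing chlorpromazine - H1 receptor interaction.
#'
#' @return list with elements `graph` (a [typed_graph()]) and `query`
#'   (a [query_graph()] inferring `binds_to` between its compound and
#'   target endpoints)
#' @export
chlorpromazine_fixture <- function() {
  graph <- typed_graph(
    vertices = data.frame(
      id = c("chlorpromazine", "trimeprazine", "T1", "T2", "T3",
             "Histamine H1 receptor"),
      type = c("Compound", "Compound", "Target", "Target", "Target", "Target")
    ),
    edges = data.frame(
      id = c("b1", "b2", "b3", "s1", "b4"),
      source = c("chlorpromazine", "chlorpromazine", "chlorpromazine",
                 "chlorpromazine", "trimeprazine"),
      target = c("T1", "T2", "T3", "trimeprazine", "Histamine H1 receptor"),
      type = c("binds_to", "binds_to", "binds_to", "similar_to", "binds_to")
    )
  )
  query <- query_graph(
    vertices = data.frame(role = c("c1", "c2", "t1"),
                          type = c("Compound", "Compound", "Target")),
    edges = data.frame(source = c("c1", "c2"), target = c("c2", "t1"),
                       type = c("similar_to", "binds_to")),
    inference = list(source = "c1", target = "t1", type = "binds_to")
  )
  list(graph = graph, query = query)
}
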