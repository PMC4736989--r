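#' Split a query once at its overlap node
#'
#' Implements one round of query splitting.  On the undirected view, the
#' most connected role becomes the overlap node (ON; ties broken by minimum
#' eccentricity, then smallest role id).  Among the remaining roles the pair
#' at maximum pairwise distance `(v1, v2)` is selected (ties: smallest sorted
#' id pair).  `D1` receives every role on the chosen shortest path from `v1`
#' to ON and `D2` every role on the path from `v2` to ON (among equal-length
#' paths the lexicographically smallest role-id sequence is taken).  Each
#' remaining role then joins the part holding more of its already-allocated
#' neighbours (ties: the smaller part, then `D1`).  An edge is allocated to a
#' part iff both its endpoints lie in that part (`D1` checked first); edges
#' spanning parts are residual.  The returned part query graphs carry their
#' full induced edge sets so that each part is searchable as a connected
#' query; `allocation` records the exact edge partition.
#'
#' @param Q a connected [query_graph()] with at least 4 roles
#' @return list with elements `D1`, `D2` (query graphs), `on` (role id),
#'   `residual` (character vector of query edge ids) and `allocation`
#'   (named character vector: edge id -> `"D1"`, `"D2"` or `"residual"`)
#' @export
split_once <- function(Q) {
  k <- nrow(Q$vertices)
  if (k < 4) stop("split_once requires a query with at least 4 roles", call. = FALSE)
  roles <- Q$vertices$role
  deg <- query_degrees(Q)
  d <- query_distances(Q)
  ecc <- apply(d, 1, max)

  cand <- roles[deg == max(deg)]
  cand <- cand[ecc[cand] == min(ecc[cand])]
  on <- sort(cand)[1]

  rest <- setdiff(roles, on)
  best <- NULL
  best_d <- -1
  for (a in sort(rest)) {
    for (b in sort(rest)) {
      if (a >= b) next
      if (d[a, b] > best_d) {
        best_d <- d[a, b]
        best <- c(a, b)
      }
    }
  }
  v1 <- best[1]; v2 <- best[2]

  d1_set <- query_shortest_path(Q, v1, on)
  d2_set <- query_shortest_path(Q, v2, on)

  adj <- query_adjacency(Q)
  repeat {
    unalloc <- setdiff(roles, union(d1_set, d2_set))
    if (length(unalloc) == 0) break
    progressed <- FALSE
    for (u in sort(unalloc)) {
      n1 <- sum(adj[[u]] %in% d1_set)
      n2 <- sum(adj[[u]] %in% d2_set)
      if (n1 == 0 && n2 == 0) next
      if (n1 > n2) {
        d1_set <- c(d1_set, u)
      } else if (n2 > n1) {
        d2_set <- c(d2_set, u)
      } else if (length(d2_set) < length(d1_set)) {
        d2_set <- c(d2_set, u)
      } else {
        d1_set <- c(d1_set, u)
      }
      progressed <- TRUE
    }
    if (!progressed) stop("internal: unallocatable roles in split_once", call. = FALSE)
  }

  if (length(d1_set) == k || length(d2_set) == k) {
    return(split_fallback(Q, on))
  }
  build_split(Q, d1_set, d2_set, on)
}

build_split <- function(Q, d1_set, d2_set, on) {
  e <- Q$edges
  in1 <- e$source %in% d1_set & e$target %in% d1_set
  in2 <- e$source %in% d2_set & e$target %in% d2_set
  allocation <- ifelse(in1, "D1", ifelse(in2, "D2", "residual"))
  names(allocation) <- e$id

  part <- function(set, induced) {
    query_graph(Q$vertices[Q$vertices$role %in% set, , drop = FALSE],
                e[induced, , drop = FALSE])
  }
  list(
    D1 = part(d1_set, in1),
    D2 = part(d2_set, in2),
    on = on,
    residual = e$id[allocation == "residual"],
    allocation = allocation
  )
}

# Degenerate-input safeguard: when the path-based allocation fails to shrink
# the query (possible when the two chosen paths overlap heavily), fall back to
# a balanced partition of the BFS subtrees hanging off the overlap node.
split_fallback <- function(Q, on) {
  adj <- query_adjacency(Q)
  roles <- Q$vertices$role
  nbs <- sort(adj[[on]])
  if (length(nbs) == 1) {
    # the hub has a single neighbour; split around that neighbour instead
    hub <- nbs[1]
    d1_set <- c(on, hub)
    d2_set <- setdiff(roles, on)
    return(build_split(Q, d1_set, d2_set, hub))
  }
  # BFS component of each neighbour with `on` removed
  comp_of <- function(start) {
    seen <- start
    frontier <- start
    while (length(frontier) > 0) {
      nxt <- setdiff(unique(unlist(adj[frontier], use.names = FALSE)), c(seen, on))
      seen <- c(seen, nxt)
      frontier <- nxt
    }
    seen
  }
  comps <- list()
  covered <- character(0)
  for (nb in nbs) {
    if (nb %in% covered) next
    cc <- comp_of(nb)
    comps[[length(comps) + 1L]] <- cc
    covered <- c(covered, cc)
  }
  sizes <- vapply(comps, length, integer(1))
  ordc <- order(-sizes)
  g1 <- character(0); g2 <- character(0)
  for (ci in ordc) {
    if (length(g1) <= length(g2)) g1 <- c(g1, comps[[ci]]) else g2 <- c(g2, comps[[ci]])
  }
  if (length(g2) == 0) {
    g2 <- g1[length(g1)]
    g1 <- g1[-length(g1)]
  }
  build_split(Q, c(on, g1), c(on, g2), on)
}

#' Recursively split a query into parts of at most 3 roles
#'
#' Applies [split_once()] until every leaf part has at most 3 roles; queries
#' with 3 or fewer roles yield the trivial single-part result.  Each query
#' edge is allocated to exactly one leaf part (both endpoints inside it) or
#' to the residual set, and the union of the leaf role sets is the query's
#' role set.
#'
#' @param Q a connected [query_graph()]
#' @return an object of class `split_result`: list with `parts` (named list
#'   of leaf query graphs), `overlap_nodes` (named character vector, one ON
#'   per non-root split, named by the split's position in the recursion
#'   tree), `residual_edges` (edge ids in no part) and `edge_allocation`
#'   (named character vector edge id -> leaf part name or `"residual"`)
#' @export
split_recursive <- function(Q) {
  parts <- list()
  ons <- character(0)
  alloc <- stats::setNames(character(length(Q$edges$id)), Q$edges$id)

  rec <- function(qg, owned, label) {
    if (nrow(qg$vertices) <= 3) {
      pname <- paste0("P", length(parts) + 1L)
      parts[[pname]] <<- qg
      if (length(owned) > 0) alloc[owned] <<- pname
      return(invisible(NULL))
    }
    s <- split_once(qg)
    ons[label] <<- s$on
    src <- stats::setNames(qg$edges$source, qg$edges$id)
    tgt <- stats::setNames(qg$edges$target, qg$edges$id)
    r1 <- s$D1$vertices$role
    r2 <- s$D2$vertices$role
    owned1 <- owned[src[owned] %in% r1 & tgt[owned] %in% r1]
    owned_rest <- setdiff(owned, owned1)
    owned2 <- owned_rest[src[owned_rest] %in% r2 & tgt[owned_rest] %in% r2]
    resid <- setdiff(owned_rest, owned2)
    if (length(resid) > 0) alloc[resid] <<- "residual"
    rec(s$D1, owned1, paste0(label, ".1"))
    rec(s$D2, owned2, paste0(label, ".2"))
  }

  rec(Q, Q$edges$id, "s")
  structure(
    list(
      parts = parts,
      overlap_nodes = ons,
      residual_edges = unname(names(alloc)[alloc == "residual"]),
      edge_allocation = alloc
    ),
    class = "split_result"
  )
}

#' @export
print.split_result <- function(x, ...) {
  sizes <- vapply(x$parts, function(p) nrow(p$vertices), integer(1))
  cat(sprintf("split_result: %d leaf part(s) of sizes {%s}, %d residual edge(s)\n",
              length(x$parts), paste(sizes, collapse = ", "),
              length(x$residual_edges)))
  invisible(x)
}

# Partial search of one part: returns bare injective vertex assignments
# (named integer vectors role -> target vertex index).  The closed-world rule
# and the exact edge bijection cannot be verified inside a part, so the
# engine runs with count-compatibility (>=) only; the joined full assignment
# is re-finalised against the complete query.
part_assignments <- function(idx, qg, matrices, cfg, full_deg_map, n_total,
                             anchor_role = NULL, anchor_cands = NULL) {
  qidx <- build_query_index(qg)
  full_deg <- unname(full_deg_map[qidx$roles])

  if (qidx$k <= 3) {
    apos <- if (!is.null(anchor_role) && anchor_role %in% qidx$roles) {
      match(anchor_role, qidx$roles)
    } else {
      which.max(qidx$deg)
    }
    cands <- if (!is.null(anchor_cands) && !is.null(anchor_role) &&
                 anchor_role %in% qidx$roles &&
                 qidx$roles[apos] == anchor_role) {
      anchor_cands
    } else {
      anchor_candidates_idx(idx, qidx, apos, matrices, cfg, n_total, full_deg)
    }
    res <- vf_engine(idx, qidx, matrices,
                     # parts must not cap: the cap applies to full mappings
                     within_cfg_uncapped(cfg), apos, cands,
                     closed_world = FALSE, emit = "assignments",
                     n_total = n_total, full_deg = full_deg)
    if (!is.null(anchor_cands) && !is.null(anchor_role) &&
        anchor_role %in% qidx$roles) {
      res <- Filter(function(a) a[anchor_role] %in% anchor_cands, res)
    }
    return(res)
  }

  s <- split_once(qg)
  on <- s$on
  first_d1 <- nrow(s$D1$vertices) <= nrow(s$D2$vertices)
  partA <- if (first_d1) s$D1 else s$D2
  partB <- if (first_d1) s$D2 else s$D1

  # seed the smaller part at the overlap node, constrained by the role's
  # full-query degree (it keeps the edge set it possessed in Q)
  asgA <- part_assignments(idx, partA, matrices, cfg, full_deg_map, n_total,
                           anchor_role = on, anchor_cands = NULL)
  if (length(asgA) == 0) return(list())
  on_imgs <- unique(vapply(asgA, function(a) a[[on]], integer(1)))
  asgB <- part_assignments(idx, partB, matrices, cfg, full_deg_map, n_total,
                           anchor_role = on, anchor_cands = on_imgs)
  joined <- join_on_overlap(asgA, asgB, on, idx, qg, s$residual, matrices, cfg)
  if (!is.null(anchor_cands) && !is.null(anchor_role) &&
      anchor_role %in% qg$vertices$role) {
    joined <- Filter(function(a) a[anchor_role] %in% anchor_cands, joined)
  }
  joined
}

within_cfg_uncapped <- function(cfg) {
  cfg$max_mappings <- Inf
  cfg
}

join_on_overlap <- function(asgA, asgB, on, idx, qg, residual_ids, matrices, cfg) {
  if (length(asgA) == 0 || length(asgB) == 0) return(list())
  rolesA <- names(asgA[[1]])
  rolesB <- names(asgB[[1]])
  shared <- intersect(rolesA, rolesB)
  onlyB <- setdiff(rolesB, rolesA)
  b_on <- vapply(asgB, function(b) b[[on]], integer(1))
  b_groups <- split(asgB, b_on)

  resid <- qg$edges[qg$edges$id %in% residual_ids, , drop = FALSE]

  out <- list()
  for (a in asgA) {
    grp <- b_groups[[as.character(a[[on]])]]
    if (is.null(grp)) next
    for (b in grp) {
      if (length(shared) > 1 && !all(a[shared] == b[shared])) next
      combined <- c(a, b[onlyB])
      if (anyDuplicated(combined)) next
      # residual edges must be realisable between the joined images
      ok <- TRUE
      if (nrow(resid) > 0) {
        key <- paste(resid$source, resid$target)
        need <- table(key)
        for (kk in names(need)) {
          st_roles <- strsplit(kk, " ", fixed = TRUE)[[1]]
          ge <- pair_edge_idx(idx, combined[[st_roles[1]]], combined[[st_roles[2]]])
          if (length(ge) < need[[kk]]) { ok <- FALSE; break }
        }
      }
      if (ok) out[[length(out) + 1L]] <- combined
    }
  }
  out
}

#' Split-and-join semantic subgraph search
#'
#' Searches a query by recursively splitting it into parts of at most 3
#' roles, searching the smaller part first seeded at the overlap node (whose
#' candidates are constrained by the role's full-query degree), seeding the
#' second part's search with the overlap images that yielded embeddings,
#' joining partial mappings that agree on the overlap node (and are
#' elsewhere disjoint), verifying residual edges, and re-checking the
#' closed-world rule and the semantic threshold on each joined full mapping,
#' whose semantic score is recomputed from scratch.  The result equals
#' [search_graph()] exactly; queries with at most 3 roles delegate to it.
#'
#' @inheritParams search_graph
#' @return list of mappings as in [search_graph()]
#' @export
split_search <- function(G, Q, matrices, cfg = search_config()) {
  validate_query_graph(Q)
  if (nrow(Q$vertices) <= 3) return(search_graph(G, Q, matrices, cfg))
  if (n_vertices(G) == 0) return(list())
  idx <- build_graph_index(G)
  qidx <- build_query_index(Q)
  n_total <- qidx$k + length(qidx$qeid)
  full_deg_map <- stats::setNames(qidx$deg, qidx$roles)

  assigns <- part_assignments(idx, Q, matrices, cfg, full_deg_map, n_total)
  res <- list()
  for (a in assigns) {
    assign_vec <- unname(a[qidx$roles])
    maps <- finalize_assignment_idx(idx, qidx, assign_vec, matrices, cfg,
                                    n_total = n_total, full_deg = qidx$deg)
    for (m in maps) {
      res[[length(res) + 1L]] <- m
      if (length(res) >= cfg$max_mappings) break
    }
    if (length(res) >= cfg$max_mappings) break
  }
  if (cfg$dedup_orbits) res <- dedup_orbit_mappings(res)
  res
}
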