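#' Select the anchor role of a query
#'
#' The search is seeded at a query vertex of the designated anchor type
#' (Compound in the drug-repositioning setting): among roles of that type the
#' one of maximum degree is chosen, ties broken by lexicographically smallest
#' role id.  If the query has no role of the anchor type, the globally
#' maximum-degree role is used and a warning signalled.
#'
#' @param Q a [query_graph()]
#' @param anchor_type vertex type name
#' @return a role id
#' @export
select_anchor <- function(Q, anchor_type) {
  deg <- query_degrees(Q)
  roles <- Q$vertices$role
  of_type <- roles[Q$vertices$type == anchor_type]
  if (length(of_type) == 0) {
    warning("query has no vertex of anchor type '", anchor_type,
            "'; falling back to the maximum-degree role", call. = FALSE)
    of_type <- roles
  }
  cand <- of_type[deg[of_type] == max(deg[of_type])]
  sort(cand)[1]
}

# Admissible-bound test used in cumulative mode: a partial element sum can
# still reach st * n_total only if topping every unscored element up to 1
# suffices.  Prunes only provably hopeless branches.
cumulative_admissible <- function(partial_sum, n_scored, n_total, st) {
  partial_sum + (n_total - n_scored) >= st * n_total - 1e-9
}

#' Initial candidate set for the anchor role
#'
#' All target vertices that pass the semantic test against the anchor's type
#' and whose total degree is at least the anchor's degree in the query
#' (`deg_G(v) >= deg_Q(v)`; degree counts edge multiplicity).  In per-element
#' mode the semantic test is `score >= st`; in cumulative mode a vertex is
#' admissible when its score could still be absorbed by a mapping whose mean
#' reaches the threshold (the admissible bound), the exact check being
#' deferred to the complete mapping.
#'
#' @param G target [typed_graph()]
#' @param Q a [query_graph()]
#' @param anchor a role id (see [select_anchor()])
#' @param matrices an [sdc_matrices()] object
#' @param cfg a [search_config()]
#' @return character vector of target vertex ids
#' @export
initial_candidates <- function(G, Q, anchor, matrices, cfg = search_config()) {
  idx <- build_graph_index(G)
  qidx <- build_query_index(Q)
  pos <- match(anchor, qidx$roles)
  if (is.na(pos)) stop("unknown anchor role: ", anchor, call. = FALSE)
  n_total <- qidx$k + length(qidx$qeid)
  cand <- anchor_candidates_idx(idx, qidx, pos, matrices, cfg, n_total,
                                full_deg = qidx$deg)
  idx$vid[cand]
}

anchor_candidates_idx <- function(idx, qidx, pos, matrices, cfg, n_total, full_deg) {
  if (idx$n == 0) return(integer(0))
  s <- score_pairs_vec(matrices$vertex, idx$vtype,
                       rep(qidx$rtype[pos], idx$n))
  ok <- if (cfg$mode == "per_element") {
    s >= cfg$st - 1e-12
  } else {
    vapply(s, function(si) cumulative_admissible(si, 1, n_total, cfg$st), logical(1))
  }
  which(ok & idx$deg_total >= full_deg[pos])
}

# Static match order: anchor first, then always a role adjacent to the
# already-ordered set, most-constrained (highest degree) first, ties by
# smallest role id.
match_order <- function(qidx, anchor_pos) {
  k <- qidx$k
  order <- integer(k)
  order[1] <- anchor_pos
  placed <- rep(FALSE, k)
  placed[anchor_pos] <- TRUE
  for (d in seq_len(k - 1)) {
    frontier <- unique(unlist(qidx$adj[order[seq_len(d)]], use.names = FALSE))
    frontier <- frontier[!placed[frontier]]
    if (length(frontier) == 0) stop("query is not connected", call. = FALSE)
    best <- frontier[qidx$deg[frontier] == max(qidx$deg[frontier])]
    nxt <- best[order(qidx$roles[best])][1]
    order[d + 1] <- nxt
    placed[nxt] <- TRUE
  }
  order
}

# Per-element feasibility of matching a group of parallel query edges onto a
# group of target edges: every query edge needs an admissible target edge and
# (under closed world, where a bijection is required) vice versa.  Exact
# bijection enumeration happens in finalize_assignment.
edge_group_feasible <- function(se_scores, st, closed_world) {
  # se_scores: matrix query edges x target edges
  if (any(apply(se_scores, 1, function(r) !any(r >= st - 1e-12)))) return(FALSE)
  if (closed_world &&
      any(apply(se_scores, 2, function(co) !any(co >= st - 1e-12)))) return(FALSE)
  TRUE
}

# The VF-style backtracking engine.  Works on integer indices; emits either
# finalized mappings or bare vertex assignments (for the splitter's partial
# searches, which cannot apply the closed-world rule).
vf_engine <- function(idx, qidx, matrices, cfg, anchor_pos, anchor_cands,
                      closed_world, emit, n_total, full_deg) {
  k <- qidx$k
  ord <- match_order(qidx, anchor_pos)
  gtypes <- unique(idx$vtype)
  vtcode <- match(idx$vtype, gtypes)
  # SV[r, t]: vertex score of query role r against target type t
  SV <- matrix(0, k, length(gtypes))
  for (r in seq_len(k)) {
    SV[r, ] <- score_pairs_vec(matrices$vertex, gtypes, rep(qidx$rtype[r], length(gtypes)))
  }
  getypes <- unique(idx$etype)
  etcode <- match(idx$etype, getypes)
  nq_e <- length(qidx$qeid)
  SE <- matrix(0, max(nq_e, 1), length(getypes))
  for (e in seq_len(nq_e)) {
    SE[e, ] <- score_pairs_vec(matrices$edge, getypes, rep(qidx$qetype[e], length(getypes)))
  }

  env <- new.env(parent = emptyenv())
  env$res <- vector("list", 64)
  env$cnt <- 0L
  env$done <- FALSE
  assign_vec <- integer(k)
  used <- logical(idx$n)

  per_element <- cfg$mode == "per_element"
  st <- cfg$st
  cap <- cfg$max_mappings

  qpair_count <- function(i, j) {
    g <- qidx$pair_edges[[paste0(i, "|", j)]]
    if (is.null(g)) integer(0) else g
  }

  emit_result <- function() {
    if (emit == "assignments") {
      env$cnt <- env$cnt + 1L
      if (env$cnt > length(env$res)) env$res <- c(env$res, vector("list", length(env$res)))
      env$res[[env$cnt]] <- stats::setNames(assign_vec, qidx$roles)
      if (env$cnt >= cap) env$done <- TRUE
    } else {
      maps <- finalize_assignment_idx(idx, qidx, assign_vec, matrices, cfg,
                                      SE, etcode, n_total, full_deg)
      for (m in maps) {
        env$cnt <- env$cnt + 1L
        if (env$cnt > length(env$res)) env$res <- c(env$res, vector("list", length(env$res)))
        env$res[[env$cnt]] <- m
        if (env$cnt >= cap) {
          env$done <- TRUE
          break
        }
      }
    }
  }

  recurse <- function(d, vsum) {
    if (env$done) return()
    r <- ord[d]
    if (d == 1) {
      pool <- anchor_cands
    } else {
      mapped_nb <- qidx$adj[[r]][assign_vec[qidx$adj[[r]]] != 0L]
      r2 <- mapped_nb[1]
      img2 <- assign_vec[r2]
      pool <- if (length(qpair_count(r2, r)) > 0) idx$nb_out[[img2]] else idx$nb_in[[img2]]
      pool <- unique(pool)
    }
    for (v in pool) {
      if (env$done) return()
      if (used[v]) next
      s <- SV[r, vtcode[v]]
      if (per_element) {
        if (s < st - 1e-12) next
      } else {
        if (!cumulative_admissible(vsum + s, d, n_total, st)) next
      }
      if (idx$deg_total[v] < full_deg[r]) next
      # self-loops
      q_loops <- qpair_count(r, r)
      g_loops <- pair_edge_idx(idx, v, v)
      if (closed_world) {
        if (length(g_loops) != length(q_loops)) next
      } else if (length(g_loops) < length(q_loops)) next
      if (per_element && length(q_loops) > 0) {
        if (length(g_loops) > 0 &&
            !edge_group_feasible(SE[q_loops, etcode[g_loops], drop = FALSE],
                                 st, closed_world)) next
      }
      # edges to / closed-world against every already-mapped role
      ok <- TRUE
      for (dd in seq_len(d - 1)) {
        r2 <- ord[dd]
        img2 <- assign_vec[r2]
        q_rt <- qpair_count(r, r2)
        q_tr <- qpair_count(r2, r)
        g_rt <- pair_edge_idx(idx, v, img2)
        g_tr <- pair_edge_idx(idx, img2, v)
        if (closed_world) {
          if (length(g_rt) != length(q_rt) || length(g_tr) != length(q_tr)) {
            ok <- FALSE; break
          }
        } else if (length(g_rt) < length(q_rt) || length(g_tr) < length(q_tr)) {
          ok <- FALSE; break
        }
        if (per_element) {
          if (length(q_rt) > 0 && length(g_rt) > 0 &&
              !edge_group_feasible(SE[q_rt, etcode[g_rt], drop = FALSE], st, closed_world)) {
            ok <- FALSE; break
          }
          if (length(q_tr) > 0 && length(g_tr) > 0 &&
              !edge_group_feasible(SE[q_tr, etcode[g_tr], drop = FALSE], st, closed_world)) {
            ok <- FALSE; break
          }
        }
      }
      if (!ok) next
      assign_vec[r] <<- v
      used[v] <<- TRUE
      if (d == k) emit_result() else recurse(d + 1, vsum + s)
      assign_vec[r] <<- 0L
      used[v] <<- FALSE
    }
  }

  if (length(anchor_cands) > 0 && k > 0) recurse(1, 0)
  if (env$cnt == 0) list() else env$res[seq_len(env$cnt)]
}

# All permutations of 1..n (n small: parallel-edge groups).
small_perms <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in small_perms(n - 1L)) {
    for (pos in seq_len(n)) {
      out[[length(out) + 1L]] <- append(p, n, after = pos - 1L)
    }
  }
  out
}

# Given a complete injective vertex assignment, verify the closed-world rule
# over every mapped ordered pair (and self-loops), enumerate the edge
# bijections group by group, apply the semantic threshold and return the
# resulting mapping objects (one per admissible edge assignment).
finalize_assignment_idx <- function(idx, qidx, assign_vec, matrices, cfg,
                                    SE = NULL, etcode = NULL,
                                    n_total = NULL, full_deg = NULL) {
  k <- qidx$k
  if (is.null(n_total)) n_total <- k + length(qidx$qeid)
  if (is.null(full_deg)) full_deg <- qidx$deg
  if (is.null(SE)) {
    getypes <- unique(idx$etype)
    etcode <- match(idx$etype, getypes)
    SE <- matrix(0, max(length(qidx$qeid), 1), length(getypes))
    for (e in seq_along(qidx$qeid)) {
      SE[e, ] <- score_pairs_vec(matrices$edge, getypes,
                                 rep(qidx$qetype[e], length(getypes)))
    }
  }
  per_element <- cfg$mode == "per_element"
  st <- cfg$st

  if (cfg$strict_degree &&
      any(idx$deg_total[assign_vec] != full_deg)) return(list())

  # vertex scores
  gtypes_of <- idx$vtype[assign_vec]
  v_scores <- score_pairs_vec(matrices$vertex, gtypes_of, qidx$rtype)
  if (per_element && any(v_scores < st - 1e-12)) return(list())

  # closed world + group collection over all ordered pairs incl. self-loops
  groups <- list()
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      qe <- qidx$pair_edges[[paste0(i, "|", j)]]
      if (is.null(qe)) qe <- integer(0)
      ge <- pair_edge_idx(idx, assign_vec[i], assign_vec[j])
      if (length(ge) != length(qe)) return(list())
      if (length(qe) > 0) groups[[length(groups) + 1L]] <- list(qe = qe, ge = ge)
    }
  }

  # per group: admissible bijections with their score vectors
  group_opts <- vector("list", length(groups))
  for (gi in seq_along(groups)) {
    qe <- groups[[gi]]$qe
    ge <- groups[[gi]]$ge
    sm <- SE[qe, etcode[ge], drop = FALSE]
    opts <- list()
    for (p in small_perms(length(qe))) {
      sc <- sm[cbind(seq_along(qe), p)]
      if (per_element && any(sc < st - 1e-12)) next
      opts[[length(opts) + 1L]] <- list(ge = ge[p], sc = sc)
    }
    if (length(opts) == 0) return(list())
    group_opts[[gi]] <- opts
  }

  q_edge_order <- unlist(lapply(groups, `[[`, "qe"))
  vmap <- stats::setNames(idx$vid[assign_vec], qidx$roles)

  results <- list()
  combine <- function(gi, chosen_ge, chosen_sc) {
    if (gi > length(group_opts)) {
      e_scores <- chosen_sc
      all_scores <- c(v_scores, e_scores)
      ss <- if (length(all_scores)) mean(all_scores) else 1
      if (!per_element && ss < st - 1e-12) return()
      emap <- stats::setNames(idx$eid[chosen_ge], qidx$qeid[q_edge_order])
      emap <- emap[order(match(names(emap), qidx$qeid))]
      results[[length(results) + 1L]] <<- list(vertices = vmap, edges = emap, ss = ss)
      return()
    }
    for (opt in group_opts[[gi]]) {
      combine(gi + 1L, c(chosen_ge, opt$ge), c(chosen_sc, opt$sc))
    }
  }
  if (length(group_opts) == 0) {
    ss <- mean(v_scores)
    if (per_element || ss >= st - 1e-12) {
      results[[1]] <- list(vertices = vmap,
                           edges = stats::setNames(character(0), character(0)),
                           ss = ss)
    }
  } else {
    combine(1L, integer(0), numeric(0))
  }
  results
}

dedup_orbit_mappings <- function(mappings) {
  if (length(mappings) == 0) return(mappings)
  keys <- vapply(mappings, function(m) {
    paste(paste(sort(unname(m$vertices)), collapse = ","),
          paste(sort(unname(m$edges)), collapse = ","), sep = ";")
  }, character(1))
  mappings[!duplicated(keys)]
}

#' Exhaustive semantic subgraph search
#'
#' The core VF-style depth-first backtracking search.  Returns exactly the
#' complete mappings of `Q` into `G` such that (a) every query edge maps to a
#' distinct target edge with matching direction, (b) the closed-world rule
#' holds — between any two mapped target vertices (and as self-loops on
#' mapped vertices) there is no target edge without a query counterpart — and
#' (c) the mapping passes the semantic threshold in the configured mode.
#' Each mapping carries its semantic score `ss`.
#'
#' The search is seeded at the anchor role ([select_anchor()]) restricted to
#' the initial candidate set ([initial_candidates()]); subsequent roles are
#' always adjacent to the mapped set and candidates are drawn from neighbours
#' of mapped images, never the whole graph.  `search_graph` performs neither
#' pruning nor splitting; see [mine_query()] for the orchestrated pipeline
#' and [split_search()] for the split variant.
#'
#' @param G target [typed_graph()]
#' @param Q a connected [query_graph()]
#' @param matrices an [sdc_matrices()] object
#' @param cfg a [search_config()]
#' @return list of mappings, each `list(vertices = , edges = , ss = )` with
#'   `vertices` a named character vector (role -> target vertex id) and
#'   `edges` likewise (query edge id -> target edge id)
#' @export
search_graph <- function(G, Q, matrices, cfg = search_config()) {
  validate_query_graph(Q)
  if (n_vertices(G) == 0) return(list())
  idx <- build_graph_index(G)
  qidx <- build_query_index(Q)
  anchor <- select_anchor(Q, cfg$anchor_type)
  anchor_pos <- match(anchor, qidx$roles)
  n_total <- qidx$k + length(qidx$qeid)
  cands <- anchor_candidates_idx(idx, qidx, anchor_pos, matrices, cfg,
                                 n_total, qidx$deg)
  res <- vf_engine(idx, qidx, matrices, cfg, anchor_pos, cands,
                   closed_world = TRUE, emit = "mappings",
                   n_total = n_total, full_deg = qidx$deg)
  if (cfg$dedup_orbits) res <- dedup_orbit_mappings(res)
  res
}

#' Brute-force reference search
#'
#' Independent oracle for testing: enumerates injective vertex assignments of
#' the query roles (in plain sorted-role BFS order, with only the
#' definitional edge-existence requirement used to prune) and filters each
#' complete assignment by the same contract as [search_graph()] — edge
#' correspondence, closed world, semantic threshold — evaluated directly from
#' the definitions.  Result set equals `search_graph`'s on any input.  Guarded
#' to small graphs.
#'
#' @inheritParams search_graph
#' @param guard maximum `n_vertices(G)` accepted (default 60)
#' @return list of mappings as in [search_graph()]
#' @export
brute_force_search <- function(G, Q, matrices, cfg = search_config(), guard = 60) {
  validate_query_graph(Q)
  if (n_vertices(G) > guard) {
    stop("brute_force_search is limited to graphs with at most ", guard,
         " vertices", call. = FALSE)
  }
  if (n_vertices(G) < nrow(Q$vertices)) return(list())
  idx <- build_graph_index(G)
  qidx <- build_query_index(Q)
  k <- qidx$k
  # BFS order from the lexicographically first role: each subsequent role has
  # a previously-placed neighbour, so the dumb edge-existence check applies.
  start <- which(qidx$roles == sort(qidx$roles)[1])
  ord <- match_order_bfs_plain(qidx, start)

  results <- list()
  assign_vec <- integer(k)
  recurse <- function(d) {
    r <- ord[d]
    for (v in seq_len(idx$n)) {
      if (v %in% assign_vec) next
      ok <- TRUE
      for (dd in seq_len(d - 1)) {
        r2 <- ord[dd]
        need_rt <- sum(qidx$qsrc == r & qidx$qtgt == r2)
        need_tr <- sum(qidx$qsrc == r2 & qidx$qtgt == r)
        have_rt <- length(pair_edge_idx(idx, v, assign_vec[r2]))
        have_tr <- length(pair_edge_idx(idx, assign_vec[r2], v))
        if (have_rt < need_rt || have_tr < need_tr) { ok <- FALSE; break }
      }
      if (!ok) next
      assign_vec[r] <<- v
      if (d == k) {
        maps <- finalize_assignment_idx(idx, qidx, assign_vec, matrices, cfg)
        for (m in maps) results[[length(results) + 1L]] <<- m
      } else {
        recurse(d + 1)
      }
      assign_vec[r] <<- 0L
    }
  }
  recurse(1)
  if (cfg$dedup_orbits) results <- dedup_orbit_mappings(results)
  results
}

match_order_bfs_plain <- function(qidx, start) {
  k <- qidx$k
  ord <- integer(k)
  ord[1] <- start
  placed <- rep(FALSE, k)
  placed[start] <- TRUE
  for (d in seq_len(k - 1)) {
    frontier <- unique(unlist(qidx$adj[ord[seq_len(d)]], use.names = FALSE))
    frontier <- frontier[!placed[frontier]]
    nxt <- frontier[order(qidx$roles[frontier])][1]
    ord[d + 1] <- nxt
    placed[nxt] <- TRUE
  }
  ord
}

#' Read inferred interactions off a set of mappings
#'
#' For each mapping, reads the images of the query's inference roles and
#' returns the (drug, target) pair the mapping infers.  Duplicates are
#' preserved; deduplication happens in the ranking stage.
#'
#' @param mappings list of mappings from [search_graph()] or [split_search()]
#' @param Q the [query_graph()]; must carry an inference annotation
#' @return data frame with columns `drug`, `target` (one row per mapping)
#' @export
mappings_to_inferences <- function(mappings, Q) {
  if (is.null(Q$inference)) {
    stop("query has no inference annotation", call. = FALSE)
  }
  if (length(mappings) == 0) {
    return(data.frame(drug = character(0), target = character(0)))
  }
  data.frame(
    drug = vapply(mappings, function(m) unname(m$vertices[Q$inference$source]), character(1)),
    target = vapply(mappings, function(m) unname(m$vertices[Q$inference$target]), character(1))
  )
}

#' Orchestrated mining of one query
#'
#' Runs the full pipeline on one query: semantic graph pruning (when enabled
#' in `cfg`), then either the split search (queries with 4+ vertices, unless
#' disabled) or the plain search, under the configured semantic threshold.
#'
#' @inheritParams search_graph
#' @return list of mappings as in [search_graph()]
#' @export
mine_query <- function(G, Q, matrices, cfg = search_config()) {
  target <- if (cfg$prune) semantic_prune(G, Q, matrices, cfg$st) else G
  use_split <- if (is.na(cfg$split)) nrow(Q$vertices) >= 4 else cfg$split
  if (use_split && nrow(Q$vertices) >= 4) {
    split_search(target, Q, matrices, cfg)
  } else {
    search_graph(target, Q, matrices, cfg)
  }
}
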