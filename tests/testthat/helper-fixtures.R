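# Shared helpers: canonical mapping keys, small random instances, and the
# held-out synthetic study used by the ranking checks.

mapping_keys <- function(maps, with_edges = TRUE) {
  if (length(maps) == 0) return(character(0))
  sort(vapply(maps, function(m) {
    v <- paste(names(m$vertices), m$vertices, sep = "=", collapse = " ")
    if (!with_edges) return(v)
    paste(v, paste(names(m$edges), m$edges, sep = "=", collapse = " "), sep = " | ")
  }, character(1)))
}

# Small 3-type test spec (|V| = 45), used by the oracle-equivalence suites.
small_spec <- function() {
  synthetic_spec(
    c(Compound = 18, Target = 14, Protein = 13),
    data.frame(
      source_type = c("Compound", "Compound", "Target", "Protein"),
      edge_type = c("similar_to", "binds_to", "is_a", "has_similar_sequence"),
      target_type = c("Compound", "Target", "Protein", "Protein"),
      count = c(16L, 22L, 13L, 11L)
    )
  )
}

# Random typed multigraph allowing self-loops and parallel edges: exercises
# engine paths the spec-driven generator (loop-free) does not.
random_multigraph <- function(seed, n = 18, m = 30,
                              vtypes = c("A", "B", "C"),
                              etypes = c("x", "y", "z")) {
  withr::with_seed(seed, {
    v <- data.frame(id = sprintf("n%02d", seq_len(n)),
                    type = sample(vtypes, n, replace = TRUE))
    e <- data.frame(
      id = sprintf("e%02d", seq_len(m)),
      source = sample(v$id, m, replace = TRUE),
      target = sample(v$id, m, replace = TRUE),
      type = sample(etypes, m, replace = TRUE)
    )
    typed_graph(v, e)
  })
}

# Random connected query over the same vocabularies, optionally with a
# self-loop and/or a duplicated (parallel) edge.
random_multigraph_query <- function(seed, n = 3, loop = FALSE, parallel = FALSE,
                                    vtypes = c("A", "B", "C"),
                                    etypes = c("x", "y", "z")) {
  withr::with_seed(seed, {
    roles <- sprintf("r%d", seq_len(n))
    types <- sample(vtypes, n, replace = TRUE)
    src <- character(0); tgt <- character(0); ety <- character(0)
    for (i in 2:n) {
      j <- if (i == 2) 1L else sample.int(i - 1L, 1)
      if (stats::runif(1) < 0.5) {
        src <- c(src, roles[j]); tgt <- c(tgt, roles[i])
      } else {
        src <- c(src, roles[i]); tgt <- c(tgt, roles[j])
      }
      ety <- c(ety, sample(etypes, 1))
    }
    if (loop) {
      src <- c(src, roles[1]); tgt <- c(tgt, roles[1])
      ety <- c(ety, sample(etypes, 1))
    }
    if (parallel) {
      src <- c(src, src[1]); tgt <- c(tgt, tgt[1])
      ety <- c(ety, sample(etypes, 1))
    }
    query_graph(data.frame(role = roles, type = types),
                data.frame(source = src, target = tgt, type = ety))
  })
}

# A graded (non-identity) SDC over the multigraph vocabularies.
graded_sdc <- function() {
  vm <- matrix(c(1, .9, 0, .9, 1, .3, 0, .3, 1), 3, 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  em <- matrix(c(1, .85, -1, .85, 1, 0, -1, 0, 1), 3, 3,
               dimnames = list(c("x", "y", "z"), c("x", "y", "z")))
  sdc_matrices(vm, em)
}

# Held-out synthetic study: compounds come in families with intra-family
# structural similarity and a pair of mutually similar family targets.
# Three of the four family compounds are binders (bind each family target
# w.p. 0.9); the fourth is a structurally similar non-binder (w.p. 0.1), the
# source of plausible-but-unsupported inferences.  A fraction of binder
# edges is held out; queries derived from the remaining graph should
# re-infer the held-out pairs and rank them above the unsupported ones,
# because genuine interactions are corroborated along several metapaths
# (compound similarity and target similarity).
held_out_study <- function(seed, n_families = 30, held_out_frac = 0.2) {
  withr::with_seed(seed, {
    sim <- list(); bind_strong <- list(); bind_weak <- list()
    all_c <- character(0); all_t <- character(0)
    for (f in seq_len(n_families)) {
      cs <- sprintf("c%02d_%d", f, 1:4)   # cs[4] is the non-binder decoy
      ts <- sprintf("t%02d_%d", f, 1:2)
      all_c <- c(all_c, cs); all_t <- c(all_t, ts)
      # binders form a similarity clique; the decoy hangs off one binder
      sim[[f]] <- rbind(
        data.frame(source = cs[c(1, 1, 2)], target = cs[c(2, 3, 3)],
                   type = "similar_to"),
        data.frame(source = cs[4], target = cs[1], type = "similar_to"),
        data.frame(source = ts[1], target = ts[2], type = "similar_to")
      )
      strong <- expand.grid(source = cs[1:3], target = ts, stringsAsFactors = FALSE)
      strong <- strong[stats::runif(nrow(strong)) < 0.9, , drop = FALSE]
      strong$type <- rep("binds_to", nrow(strong))
      bind_strong[[f]] <- strong
      weak <- expand.grid(source = cs[4], target = ts, stringsAsFactors = FALSE)
      weak <- weak[stats::runif(nrow(weak)) < 0.1, , drop = FALSE]
      weak$type <- rep("binds_to", nrow(weak))
      bind_weak[[f]] <- weak
    }
    vertices <- data.frame(
      id = c(all_c, all_t),
      type = rep(c("Compound", "Target"), c(length(all_c), length(all_t)))
    )
    edges <- rbind(do.call(rbind, sim), do.call(rbind, bind_strong),
                   do.call(rbind, bind_weak))
    edges <- cbind(id = sprintf("e%d", seq_len(nrow(edges))), edges)
    G_full <- typed_graph(vertices, edges)

    n_sim <- nrow(do.call(rbind, sim))
    n_strong <- nrow(do.call(rbind, bind_strong))
    strong_ids <- edges$id[(n_sim + 1):(n_sim + n_strong)]
    held <- sample(strong_ids, round(held_out_frac * length(strong_ids)))
    keep <- !(G_full$edges$id %in% held)
    G <- typed_graph(G_full$vertices, G_full$edges[keep, , drop = FALSE])
    held_pairs <- data.frame(
      drug = G_full$edges$source[G_full$edges$id %in% held],
      target = G_full$edges$target[G_full$edges$id %in% held]
    )
    list(G = G, held_pairs = held_pairs)
  })
}
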