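two_hop_graph <- function() {
  typed_graph(
    vertices = data.frame(id = c("a", "c", "b", "island"),
                          type = c("Compound", "Compound", "Target", "Disease")),
    edges = data.frame(id = c("e1", "e2"),
                       source = c("a", "c"), target = c("c", "b"),
                       type = c("similar_to", "binds_to"))
  )
}

test_that("relevant pairs need both endpoints present and no interaction edge", {
  g <- two_hop_graph()
  cand <- data.frame(
    drug = c("a", "c", "ghost"),
    target = c("b", "b", "b")
  )
  rel <- relevant_interactions(g, cand, "binds_to")
  # (a, b): both present, not linked by binds_to -> retained
  # (c, b): existing binds_to edge -> dropped; (ghost, b): absent -> dropped
  expect_equal(rel$pairs, data.frame(drug = "a", target = "b"))
})

test_that("shortest semantic paths are minimal, deterministic and typed", {
  g <- two_hop_graph()
  p <- shortest_semantic_path(g, "a", "b")
  expect_equal(p$vertex_ids, c("a", "c", "b"))
  expect_equal(p$edges$type, c("similar_to", "binds_to"))
  expect_error(shortest_semantic_path(g, "a", "island"), "no path")
  expect_error(shortest_semantic_path(g, "a", "ghost"), "unknown vertex")

  # two equal-length routes: the lexicographically smaller id sequence wins
  tie <- typed_graph(
    vertices = data.frame(id = c("s", "m1", "m2", "t"), type = "X"),
    edges = data.frame(id = paste0("e", 1:4),
                       source = c("s", "m1", "s", "m2"),
                       target = c("m1", "t", "m2", "t"), type = "r")
  )
  expect_equal(shortest_semantic_path(tie, "s", "t")$vertex_ids,
               c("s", "m1", "t"))
})

test_that("paths convert to type-level queries with the inference annotation", {
  g <- two_hop_graph()
  q <- path_to_query(shortest_semantic_path(g, "a", "b"), "binds_to")
  expect_equal(q$vertices$type, c("Compound", "Compound", "Target"))
  expect_equal(q$edges$type, c("similar_to", "binds_to"))
  expect_equal(q$inference$source, "r1")
  expect_equal(q$inference$target, "r3")
  # it is exactly the guilt-by-association triad
  fx <- chlorpromazine_fixture()
  expect_length(dedup_queries(list(q, fx$query)), 1)

  # one-edge path gives a 2-role query
  p1 <- shortest_semantic_path(g, "a", "c")
  expect_equal(nrow(path_to_query(p1, "binds_to")$vertices), 2)

  # revisiting a type keeps distinct roles
  rep_g <- typed_graph(
    vertices = data.frame(id = c("c1", "t1", "c2"),
                          type = c("Compound", "Target", "Compound")),
    edges = data.frame(id = c("e1", "e2"), source = c("c1", "c2"),
                       target = c("t1", "t1"), type = "binds_to")
  )
  q3 <- path_to_query(shortest_semantic_path(rep_g, "c1", "c2"), "similar_to")
  expect_equal(q3$vertices$type, c("Compound", "Target", "Compound"))
  expect_equal(nrow(q3$vertices), 3)
})

test_that("dedup groups by typed isomorphism, direction matters", {
  mk_triad <- function(flip = FALSE) {
    query_graph(
      vertices = data.frame(role = c("x", "y", "z"),
                            type = c("Compound", "Compound", "Target")),
      edges = data.frame(
        source = if (flip) c("y", "y") else c("x", "y"),
        target = if (flip) c("x", "z") else c("y", "z"),
        type = c("similar_to", "binds_to")
      ),
      inference = list(source = "x", target = "z", type = "binds_to")
    )
  }
  same1 <- mk_triad(); same2 <- mk_triad(); flipped <- mk_triad(flip = TRUE)
  res <- dedup_queries(list(same1, same2, flipped))
  expect_length(res, 2)
  mult <- sort(vapply(res, function(e) e$multiplicity, integer(1)))
  expect_equal(mult, c(1L, 2L))
  expect_length(dedup_queries(list()), 0)
})

test_that("multiplicities sum to the retained input count and survive role shuffles", {
  withr::with_seed(5, {
    qs <- lapply(1:12, function(i) {
      random_query(3 + i %% 3, vertex_types = c("A", "B"),
                   edge_types = c("x", "y"), extra_edges = i %% 2, seed = i %% 4)
    })
    # shuffle role labels of half of them: class membership must not change
    shuffle_roles <- function(q) {
      perm <- sample(q$vertices$role)
      map <- stats::setNames(perm, q$vertices$role)
      query_graph(
        data.frame(role = unname(map[q$vertices$role]), type = q$vertices$type),
        data.frame(source = unname(map[q$edges$source]),
                   target = unname(map[q$edges$target]), type = q$edges$type)
      )
    }
    qs_shuffled <- lapply(qs, shuffle_roles)
    r1 <- dedup_queries(qs)
    r2 <- dedup_queries(qs_shuffled)
    expect_equal(sum(vapply(r1, function(e) e$multiplicity, integer(1))), 12L)
    expect_equal(sort(vapply(r1, function(e) e$multiplicity, integer(1))),
                 sort(vapply(r2, function(e) e$multiplicity, integer(1))))
  })
})

test_that("oversized queries are discarded with a warning", {
  big <- path_to_query(
    structure(list(
      vertex_ids = sprintf("n%d", 1:6),
      vertex_types = rep("X", 6),
      edges = data.frame(id = paste0("e", 1:5),
                         source = sprintf("n%d", 1:5),
                         target = sprintf("n%d", 2:6), type = "r")
    ), class = "semantic_path"),
    "r"
  )
  expect_warning(res <- dedup_queries(list(big), max_vertices = 4), "discarded")
  expect_length(res, 0)
})

test_that("derive_queries runs the whole pipeline and skips unreachable pairs", {
  g <- typed_graph(
    vertices = data.frame(
      id = c("d1", "c1", "t1", "d2", "c2", "t2", "far"),
      type = c("Compound", "Compound", "Target",
               "Compound", "Compound", "Target", "Target")
    ),
    edges = data.frame(
      id = paste0("e", 1:4),
      source = c("d1", "c1", "d2", "c2"),
      target = c("c1", "t1", "c2", "t2"),
      type = c("similar_to", "binds_to", "similar_to", "binds_to")
    )
  )
  pairs <- data.frame(drug = c("d1", "d2", "d1"),
                      target = c("t1", "t2", "far"))
  res <- derive_queries(g, pairs, "binds_to")
  # the two 2-hop pairs share one isomorphism class; far is unreachable
  expect_length(res, 1)
  expect_equal(res[[1]]$multiplicity, 2L)
  expect_equal(attr(res, "skipped")$target, "far")
})
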