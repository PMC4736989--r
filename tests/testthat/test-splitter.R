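path_query <- function(n, type = "A", etype = "x") {
  roles <- sprintf("v%d", seq_len(n))
  query_graph(
    vertices = data.frame(role = roles, type = type),
    edges = data.frame(source = roles[-n], target = roles[-1], type = etype)
  )
}

test_that("a 5-path splits at its centre into two 3-role parts", {
  q <- path_query(5)
  s <- split_once(q)
  expect_equal(s$on, "v3")  # degree tie among v2,v3,v4 broken by eccentricity
  expect_setequal(s$D1$vertices$role, c("v1", "v2", "v3"))
  expect_setequal(s$D2$vertices$role, c("v3", "v4", "v5"))
  expect_length(s$residual, 0)
})

test_that("splitting requires at least 4 roles", {
  expect_error(split_once(path_query(3)), "at least 4")
  sr <- split_recursive(path_query(3))
  expect_length(sr$parts, 1)
  expect_setequal(sr$parts[[1]]$vertices$role, c("v1", "v2", "v3"))
})

test_that("a 6-path recursively splits into leaves of at most 3 roles", {
  sr <- split_recursive(path_query(6))
  sizes <- sort(vapply(sr$parts, function(p) nrow(p$vertices), integer(1)))
  expect_true(all(sizes <= 3))
  expect_setequal(unlist(lapply(sr$parts, function(p) p$vertices$role)),
                  sprintf("v%d", 1:6))
})

test_that("a triangle with a pendant splits at the hub", {
  q <- query_graph(
    vertices = data.frame(role = c("a", "b", "c", "d"), type = "A"),
    edges = data.frame(source = c("a", "b", "c", "a"),
                       target = c("b", "c", "a", "d"), type = "x")
  )
  s <- split_once(q)
  expect_equal(s$on, "a")  # degree 3
  expect_true("a" %in% s$D1$vertices$role && "a" %in% s$D2$vertices$role)
  # split search equals plain search on a small graph containing the pattern
  G <- random_multigraph(3, n = 16, m = 34, vtypes = "A", etypes = "x")
  m <- identity_sdc("A", "x")
  cfg <- search_config(st = 0.8, anchor_type = "A")
  expect_identical(mapping_keys(split_search(G, q, m, cfg)),
                   mapping_keys(brute_force_search(G, q, m, cfg)))
})

test_that("split invariants hold over random connected queries", {
  for (s in 1:40) {
    Q <- random_query(4 + s %% 6, vertex_types = c("A", "B", "C"),
                      edge_types = c("x", "y"), extra_edges = s %% 4, seed = s)
    sr <- split_recursive(Q)
    sizes <- vapply(sr$parts, function(p) nrow(p$vertices), integer(1))
    expect_true(all(sizes <= 3))
    # vertex union equals V(Q)
    expect_setequal(unlist(lapply(sr$parts, function(p) p$vertices$role)),
                    Q$vertices$role)
    # each edge in exactly one part or residual
    al <- sr$edge_allocation
    expect_setequal(names(al), Q$edges$id)
    expect_true(all(al %in% c(names(sr$parts), "residual")))
    for (eid in names(al)) {
      if (al[[eid]] == "residual") next
      part <- sr$parts[[al[[eid]]]]
      e <- Q$edges[Q$edges$id == eid, ]
      expect_true(all(c(e$source, e$target) %in% part$vertices$role))
    }
    # parts are connected query graphs (constructor enforces connectivity)
    for (p in sr$parts) expect_s3_class(p, "query_graph")
  }
})

test_that("split search equals plain search over random instances", {
  spec <- small_spec()
  for (s in 1:25) {
    G <- random_graph(spec, seed = s)
    mg <- metagraph(G)
    m <- identity_sdc(G$vertex_types, G$edge_types)
    Q <- suppressWarnings(
      random_query(4 + s %% 6, metagraph = mg, extra_edges = s %% 3, seed = s + 300)
    )
    for (mode in c("per_element", "cumulative")) {
      cfg <- search_config(st = if (mode == "per_element") 0.8 else 0.5,
                           mode = mode, anchor_type = "Compound")
      plain <- suppressWarnings(search_graph(G, Q, m, cfg))
      split <- suppressWarnings(split_search(G, Q, m, cfg))
      expect_identical(mapping_keys(plain, with_edges = FALSE),
                       mapping_keys(split, with_edges = FALSE))
      expect_identical(mapping_keys(plain), mapping_keys(split))
    }
  }
})

test_that("residual (cross-part) edges are verified on the joined mapping", {
  # 4-cycle query: one edge necessarily spans the two parts
  q <- query_graph(
    vertices = data.frame(role = c("a", "b", "c", "d"), type = "A"),
    edges = data.frame(source = c("a", "b", "c", "d"),
                       target = c("b", "c", "d", "a"), type = "x")
  )
  m <- identity_sdc("A", "x")
  cfg <- search_config(st = 0.8, anchor_type = "A")
  # a true 4-cycle is found ...
  cyc <- typed_graph(
    vertices = data.frame(id = c("g1", "g2", "g3", "g4"), type = "A"),
    edges = data.frame(id = paste0("e", 1:4),
                       source = c("g1", "g2", "g3", "g4"),
                       target = c("g2", "g3", "g4", "g1"), type = "x")
  )
  expect_gt(length(split_search(cyc, q, m, cfg)), 0)
  # ... but an open 4-path (missing the closing residual edge) is not
  open4 <- typed_graph(
    vertices = data.frame(id = c("g1", "g2", "g3", "g4"), type = "A"),
    edges = data.frame(id = paste0("e", 1:3),
                       source = c("g1", "g2", "g3"),
                       target = c("g2", "g3", "g4"), type = "x")
  )
  expect_length(split_search(open4, q, m, cfg), 0)
  # and both agree with brute force on random graphs
  for (s in 1:5) {
    G <- random_multigraph(s + 60, n = 14, m = 30, vtypes = "A", etypes = "x")
    expect_identical(mapping_keys(split_search(G, q, m, cfg)),
                     mapping_keys(brute_force_search(G, q, m, cfg)))
  }
})

test_that("queries of up to 3 roles delegate to the plain search", {
  fx <- chlorpromazine_fixture()
  m <- identity_sdc(fx$graph$vertex_types, fx$graph$edge_types)
  cfg <- search_config()
  expect_identical(mapping_keys(split_search(fx$graph, fx$query, m, cfg)),
                   mapping_keys(search_graph(fx$graph, fx$query, m, cfg)))
})

test_that("9-role queries reach leaves of at most 3 in at least two rounds", {
  sr <- split_recursive(path_query(9))
  expect_gte(length(sr$parts), 3)
  expect_true(all(vapply(sr$parts, function(p) nrow(p$vertices), integer(1)) <= 3))
  expect_gte(length(sr$overlap_nodes), 2)   # nested splits occurred
})
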