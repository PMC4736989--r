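test_that("anchor selection prefers the max-degree role of the anchor type", {
  q <- query_graph(
    vertices = data.frame(role = c("a", "b", "t"),
                          type = c("Compound", "Compound", "Target")),
    edges = data.frame(source = c("a", "b", "b"), target = c("b", "t", "a"),
                       type = "x")
  )
  expect_equal(select_anchor(q, "Compound"), "b")  # degree 3 beats 2

  tie <- query_graph(
    vertices = data.frame(role = c("c2", "c1", "t"),
                          type = c("Compound", "Compound", "Target")),
    edges = data.frame(source = c("c1", "c2"), target = c("t", "t"), type = "x")
  )
  expect_equal(select_anchor(tie, "Compound"), "c1")  # tie broken by role id

  no_comp <- query_graph(
    vertices = data.frame(role = c("p", "q"), type = c("Target", "Target")),
    edges = data.frame(source = "p", target = "q", type = "x")
  )
  expect_warning(a <- select_anchor(no_comp, "Compound"), "anchor type")
  expect_equal(a, "p")
})

test_that("initial candidates respect the degree and semantic rules", {
  g <- typed_graph(
    vertices = data.frame(
      id = c("rich", "poor", "sick"),
      type = c("Compound", "Compound", "Disease")
    ),
    edges = data.frame(id = paste0("e", 1:3),
                       source = c("rich", "rich", "rich"),
                       target = c("poor", "sick", "sick"), type = "x")
  )
  q <- query_graph(
    vertices = data.frame(role = c("c", "d"), type = c("Compound", "Compound")),
    edges = data.frame(source = c("c", "c"), target = c("d", "d"), type = "x")
  )
  m <- identity_sdc(c("Compound", "Disease"), "x")
  cfg <- search_config(st = 0.8)
  anchor <- select_anchor(q, "Compound")
  cands <- initial_candidates(g, q, anchor, m, cfg)
  expect_setequal(cands, "rich")   # poor: degree 1 < 2; sick: wrong type
})

test_that("the guilt-by-association fixture yields exactly one mapping", {
  fx <- chlorpromazine_fixture()
  m <- identity_sdc(fx$graph$vertex_types, fx$graph$edge_types)
  cfg <- search_config(st = 0.8, mode = "per_element")
  res <- search_graph(fx$graph, fx$query, m, cfg)
  expect_length(res, 1)
  expect_equal(unname(res[[1]]$vertices["c1"]), "chlorpromazine")
  expect_equal(unname(res[[1]]$vertices["c2"]), "trimeprazine")
  expect_equal(unname(res[[1]]$vertices["t1"]), "Histamine H1 receptor")
  expect_identical(mapping_keys(res),
                   mapping_keys(brute_force_search(fx$graph, fx$query, m, cfg)))

  inf <- mappings_to_inferences(res, fx$query)
  expect_equal(inf$drug, "chlorpromazine")
  expect_equal(inf$target, "Histamine H1 receptor")
})

test_that("an extra edge between mapped vertices violates the closed world", {
  fx <- chlorpromazine_fixture()
  g <- fx$graph
  g$edges <- rbind(g$edges[c("id", "source", "target", "type")],
                   data.frame(id = "extra", source = "chlorpromazine",
                              target = "Histamine H1 receptor", type = "binds_to"))
  g <- typed_graph(g$vertices[c("id", "type")], g$edges)
  m <- identity_sdc(g$vertex_types, g$edge_types)
  cfg <- search_config(st = 0.8)
  expect_length(search_graph(g, fx$query, m, cfg), 0)
  expect_length(brute_force_search(g, fx$query, m, cfg), 0)
})

test_that("degenerate inputs are handled", {
  fx <- chlorpromazine_fixture()
  m <- identity_sdc("Compound", "x")
  expect_length(search_graph(typed_graph(), fx$query, m, search_config()), 0)
  # query larger than the target graph
  small <- typed_graph(vertices = data.frame(id = "only", type = "Compound"))
  expect_length(brute_force_search(small, fx$query, m, search_config()), 0)
  expect_error(brute_force_search(random_multigraph(1, n = 70, m = 10),
                                  fx$query, m, search_config(), guard = 60),
               "at most")
})

test_that("search agrees with the brute-force oracle over random instances", {
  spec <- small_spec()
  checked <- 0L
  nonzero <- 0L
  for (s in 1:25) {
    G <- random_graph(spec, seed = s)
    mg <- metagraph(G)
    m <- identity_sdc(G$vertex_types, G$edge_types)
    Q <- suppressWarnings(
      random_query(3 + s %% 4, metagraph = mg, extra_edges = s %% 3, seed = s + 100)
    )
    for (mode in c("per_element", "cumulative")) {
      cfg <- search_config(st = if (mode == "per_element") 0.8 else 0.5,
                           mode = mode, anchor_type = "Compound")
      fast <- suppressWarnings(search_graph(G, Q, m, cfg))
      slow <- suppressWarnings(brute_force_search(G, Q, m, cfg))
      expect_identical(mapping_keys(fast), mapping_keys(slow))
      checked <- checked + 1L
      if (length(slow) > 0) nonzero <- nonzero + 1L
    }
  }
  expect_gte(checked, 50L)
  expect_gt(nonzero, 5L)   # the suite exercises non-trivial instances
})

test_that("oracle equivalence holds on multigraphs with loops and parallels under a graded SDC", {
  mats <- graded_sdc()
  for (s in 1:12) {
    G <- random_multigraph(s)
    Q <- random_multigraph_query(s + 500, n = 3 + s %% 2,
                                 loop = s %% 3 == 0, parallel = s %% 4 == 0)
    for (mode in c("per_element", "cumulative")) {
      cfg <- search_config(st = if (mode == "per_element") 0.8 else 0.6,
                           mode = mode, anchor_type = "A")
      fast <- suppressWarnings(search_graph(G, Q, mats, cfg))
      slow <- suppressWarnings(brute_force_search(G, Q, mats, cfg))
      expect_identical(mapping_keys(fast), mapping_keys(slow))
    }
  }
})

test_that("returned mappings are induced and pass their threshold mode", {
  spec <- small_spec()
  G <- random_graph(spec, seed = 13)
  m <- identity_sdc(G$vertex_types, G$edge_types)
  Q <- suppressWarnings(random_query(4, metagraph = metagraph(G), seed = 9))
  cfg <- search_config(st = 0.8)
  res <- suppressWarnings(search_graph(G, Q, m, cfg))
  for (mp in res) {
    imgs <- unname(mp$vertices)
    # no edge between mapped vertices outside the mapping's edge image
    seen <- character(0)
    for (u in imgs) for (v in imgs) {
      if (u < v || u == v) {
        eb <- edges_between(G, u, v)
        seen <- union(seen, eb$id)
      }
    }
    expect_setequal(seen, unname(mp$edges))
    expect_true(mp$ss >= cfg$st - 1e-12)
  }
})

test_that("raising the threshold never adds mappings", {
  G <- random_multigraph(41, n = 20, m = 35)
  Q <- random_multigraph_query(42, n = 3)
  mats <- graded_sdc()
  prev <- NULL
  for (st in c(0, 0.3, 0.6, 0.9, 1)) {
    cfg <- search_config(st = st, mode = "cumulative", anchor_type = "A")
    cur <- mapping_keys(suppressWarnings(search_graph(G, Q, mats, cfg)))
    if (!is.null(prev)) expect_true(all(cur %in% prev))
    prev <- cur
  }
})

test_that("planting k disjoint rigid instances adds exactly k mappings", {
  spec <- small_spec()
  Q <- query_graph(
    vertices = data.frame(role = c("c", "t", "p"),
                          type = c("Compound", "Target", "Protein")),
    edges = data.frame(source = c("c", "t"), target = c("t", "p"),
                       type = c("binds_to", "is_a"))
  )
  expect_true(query_is_rigid(Q))
  for (s in 1:10) {
    G <- random_graph(spec, seed = s)
    m <- identity_sdc(G$vertex_types, G$edge_types)
    k <- 1 + s %% 4
    Gs <- plant_instances(G, Q, k)
    for (mode in c("per_element", "cumulative")) {
      cfg <- search_config(st = 0.8, mode = mode)
      base <- length(search_graph(G, Q, m, cfg))
      spiked <- length(search_graph(Gs, Q, m, cfg))
      expect_equal(spiked - base, k)
    }
  }
})

test_that("parallel query edges map to distinct parallel target edges", {
  g <- typed_graph(
    vertices = data.frame(id = c("u", "v", "w"), type = c("A", "B", "B")),
    edges = data.frame(id = c("p1", "p2", "q1"),
                       source = c("u", "u", "u"),
                       target = c("v", "v", "w"),
                       type = c("x", "x", "x"))
  )
  q2 <- query_graph(
    vertices = data.frame(role = c("r", "s"), type = c("A", "B")),
    edges = data.frame(source = c("r", "r"), target = c("s", "s"), type = "x")
  )
  m <- identity_sdc(c("A", "B"), "x")
  res <- search_graph(g, q2, m, search_config(st = 0.8, anchor_type = "A"))
  # only u->v carries two parallels; both edge bijections count as mappings
  expect_length(res, 2)
  for (mp in res) expect_length(unique(mp$edges), 2)
  # single-edge query on the parallel pair fails closed world
  q1 <- query_graph(
    vertices = data.frame(role = c("r", "s"), type = c("A", "B")),
    edges = data.frame(source = "r", target = "s", type = "x")
  )
  res1 <- search_graph(g, q1, m, search_config(st = 0.8, anchor_type = "A"))
  expect_equal(unname(vapply(res1, function(mp) mp$vertices[["s"]], character(1))), "w")
})

test_that("query self-loops must map to target self-loops", {
  g <- typed_graph(
    vertices = data.frame(id = c("a", "b", "c"), type = "A"),
    edges = data.frame(id = c("l", "e1", "e2"),
                       source = c("a", "a", "b"),
                       target = c("a", "b", "c"),
                       type = "x")
  )
  q <- query_graph(
    vertices = data.frame(role = c("r", "s"), type = c("A", "A")),
    edges = data.frame(source = c("r", "r"), target = c("r", "s"), type = "x")
  )
  m <- identity_sdc("A", "x")
  res <- search_graph(g, q, m, search_config(st = 0.8, anchor_type = "A"))
  expect_length(res, 1)
  expect_equal(unname(res[[1]]$vertices["r"]), "a")
})

test_that("orbit deduplication collapses automorphic re-embeddings", {
  g <- typed_graph(
    vertices = data.frame(id = c("x", "y"), type = "A"),
    edges = data.frame(id = c("f", "b"), source = c("x", "y"),
                       target = c("y", "x"), type = "x")
  )
  q <- query_graph(
    vertices = data.frame(role = c("r", "s"), type = c("A", "A")),
    edges = data.frame(source = c("r", "s"), target = c("s", "r"), type = "x")
  )
  m <- identity_sdc("A", "x")
  raw <- search_graph(g, q, m, search_config(st = 0.8, anchor_type = "A"))
  expect_length(raw, 2)   # the 2-cycle embeds both ways round
  dedup <- search_graph(g, q, m,
                        search_config(st = 0.8, anchor_type = "A",
                                      dedup_orbits = TRUE))
  expect_length(dedup, 1)
})

test_that("strict degree mode additionally requires degree equality", {
  fx <- chlorpromazine_fixture()
  m <- identity_sdc(fx$graph$vertex_types, fx$graph$edge_types)
  # chlorpromazine has degree 4 in G but role c1 has degree 1 in Q
  res <- search_graph(fx$graph, fx$query, m,
                      search_config(st = 0.8, strict_degree = TRUE))
  expect_length(res, 0)
})

test_that("the mapping cap truncates the result set", {
  G <- random_multigraph(8, n = 20, m = 40)
  Q <- random_multigraph_query(8, n = 3)
  mats <- graded_sdc()
  all_maps <- suppressWarnings(search_graph(G, Q, mats,
    search_config(st = 0, mode = "cumulative", anchor_type = "A")))
  if (length(all_maps) >= 2) {
    capped <- suppressWarnings(search_graph(G, Q, mats,
      search_config(st = 0, mode = "cumulative", anchor_type = "A",
                    max_mappings = 2)))
    expect_length(capped, 2)
  }
})

test_that("mappings_to_inferences requires an inference annotation", {
  q <- query_graph(
    vertices = data.frame(role = c("a", "b"), type = c("A", "B")),
    edges = data.frame(source = "a", target = "b", type = "x")
  )
  expect_error(mappings_to_inferences(list(), q), "inference")
  fx <- chlorpromazine_fixture()
  expect_equal(nrow(mappings_to_inferences(list(), fx$query)), 0)
})
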