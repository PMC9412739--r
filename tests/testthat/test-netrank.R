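test_that("set intersection and Venn regions are exact", {
  out <- intersect_sets(list(a = c("A", "B", "C"), b = c("B", "C", "D"),
                             c = c("C", "E")))
  expect_equal(out$intersection, "C")
  expect_equal(nrow(out$regions), 7)
  expect_equal(sum(out$regions$count), 5)   # A B C D E each in one region
  only_a <- out$regions$count[out$regions$a & !out$regions$b & !out$regions$c]
  expect_equal(only_a, 1)                   # {A}

  expect_equal(intersect_sets(list(x = "A", y = "B"))$intersection,
               character(0))
  expect_error(intersect_sets(list(a = "A")), ">= 2")
})

test_that("random set intersections match a brute-force membership scan", {
  set.seed(31)
  for (i in 1:10) {
    pool <- paste0("G", 1:40)
    sets <- lapply(1:3, function(j) sample(pool, sample(5:25, 1)))
    names(sets) <- c("s1", "s2", "s3")
    out <- intersect_sets(sets)
    brute <- pool[vapply(pool, function(g)
      all(vapply(sets, function(s) g %in% s, logical(1))), logical(1))]
    expect_setequal(out$intersection, brute)
  }
})

test_that("hub scores are exact on canonical small graphs", {
  tri <- igraph::make_ring(3)
  igraph::V(tri)$name <- c("a", "b", "c")
  rk <- hub_scores(tri)
  expect_equal(rk$mcc, rep(2, 3))          # one 3-clique, (3-1)! = 2
  expect_equal(rk$degree, rep(2, 3))

  star <- igraph::make_star(5, mode = "undirected", center = 1)
  igraph::V(star)$name <- c("hub", paste0("leaf", 1:4))
  rs <- hub_scores(star)
  expect_equal(which.max(rs$degree), 1)
  expect_equal(which.max(rs$betweenness), 1)
  expect_equal(rs$mcc, c(4, 1, 1, 1, 1))   # four maximal 2-cliques at hub
  expect_equal(length(unique(rs$closeness[-1])), 1)  # leaves tie
})

test_that("MCC, betweenness and closeness match brute-force oracles", {
  set.seed(33)
  for (i in 1:30) {
    n <- sample(4:10, 1)
    A <- random_adjacency(n, p_edge = 0.45)
    g <- adjacency_to_igraph(A)
    rk <- hub_scores(g, metrics = c("mcc", "closeness", "betweenness",
                                    "degree"))
    expect_equal(rk$mcc, mcc_oracle(A), tolerance = 1e-9)
    expect_equal(rk$betweenness, betweenness_oracle(A), tolerance = 1e-9)
    expect_equal(rk$closeness, harmonic_oracle(A), tolerance = 1e-9)
    expect_equal(rk$degree, unname(rowSums(A)))
  }
})

test_that("scores stay finite on disconnected graphs", {
  g <- igraph::graph_from_edgelist(rbind(c("a", "b"), c("c", "d")),
                                   directed = FALSE)
  g <- igraph::add_vertices(g, 1, name = "iso")
  rk <- hub_scores(g, epc_iterations = 50)
  expect_true(all(is.finite(as.matrix(rk[, -1]))))
  expect_equal(rk$eccentricity[rk$node == "iso"], 0)
  expect_equal(rk$degree[rk$node == "iso"], 0)
})

test_that("EPC is seeded-reproducible and stable across seeds", {
  gg <- make_graph(n_nodes = 30, n_edges = 55, clique_size = 4, seed = 2)
  r1 <- hub_scores(gg$graph, metrics = "epc", seed = 5)
  r2 <- hub_scores(gg$graph, metrics = "epc", seed = 5)
  expect_identical(r1$epc, r2$epc)
  reps <- vapply(1:6, function(s)
    hub_scores(gg$graph, metrics = "epc", epc_iterations = 1000,
               seed = s)$epc, numeric(30))
  cv <- apply(reps, 1, sd) / rowMeans(reps)
  expect_lt(max(cv), 0.05)
})

test_that("consensus top-k is the intersection of per-metric top lists", {
  gg <- make_graph(seed = 7)
  rk <- hub_scores(gg$graph, seed = 7)
  cons <- consensus_top_k(rk, 7)
  for (m in names(cons$top)) {
    expect_length(cons$top[[m]], 7)
    expect_true(all(cons$consensus %in% cons$top[[m]]))
  }
  all_nodes <- consensus_top_k(rk, nrow(rk))
  expect_setequal(all_nodes$consensus, rk$node)
  expect_error(consensus_top_k(rk, nrow(rk) + 1), "exceeds")

  # metrics that agree on a clique-plus-tail graph give the clique
  g <- igraph::graph_from_edgelist(
    rbind(t(combn(paste0("k", 1:4), 2)),
          c("k1", "t1"), c("t1", "t2"), c("t2", "t3")), directed = FALSE)
  rk2 <- hub_scores(g, metrics = c("mcc", "degree"))
  expect_setequal(consensus_top_k(rk2, 4)$consensus, paste0("k", 1:4))
})

test_that("hypergeometric enrichment equals the combinatorial closed form", {
  # 5 of 10 query genes in a 20-gene term, background 1000
  term <- paste0("T", 1:20)
  query <- c(term[1:5], paste0("Q", 1:5))
  bg <- unique(c(term, query, paste0("B", 1:975)))
  res <- hypergeom_enrich(query, list(term1 = term), bg, filter = FALSE)
  expect_equal(res$p, hyper_tail_oracle(5, 20, length(bg), 10),
               tolerance = 1e-12)
  expect_true(res$significant)

  # query == term == background: no enrichment possible
  res2 <- hypergeom_enrich(term, list(t = term), term, filter = FALSE)
  expect_equal(res2$p, 1)
  expect_false(res2$significant)

  expect_error(hypergeom_enrich("A", list(t = c("A", "B")), background = 1),
               "larger than the background")
  expect_error(hypergeom_enrich("Z", list(t = "A"), c("A", "B")),
               "outside the background")
})

test_that("BH adjustment matches the textbook step-up on random vectors", {
  set.seed(35)
  for (i in 1:10) {
    p <- runif(sample(5:40, 1))^sample(1:3, 1)
    expect_equal(p.adjust(p, "BH"), bh_oracle(p), tolerance = 1e-12)
  }
  # and the q column in enrichment output is that adjustment
  sets <- lapply(1:8, function(i) paste0("G", sample(100, 20)))
  names(sets) <- paste0("t", 1:8)
  bg <- paste0("G", 1:100)
  q <- paste0("G", sample(100, 15))
  res <- hypergeom_enrich(q, sets, bg, filter = FALSE)
  expect_equal(res$q, bh_oracle(res$p)[order(order(res$p, res$term))],
               tolerance = 1e-12)
})

test_that("raw p-values are calibrated under random queries", {
  set.seed(37)
  bg <- paste0("G", 1:500)
  sets <- lapply(1:20, function(i) sample(bg, 40))
  names(sets) <- paste0("t", 1:20)
  hits <- replicate(50, {
    q <- sample(bg, 25)
    mean(hypergeom_enrich(q, sets, bg, filter = FALSE)$p < 0.05)
  })
  expect_lt(mean(hits), 0.10)  # ~5% nominal for a discrete test
})

test_that("edge lists and GMT files parse with validation", {
  tmp <- tempfile(fileext = ".tsv")
  writeLines(c("nodeA\tnodeB\tweight", "a\tb\t0.9", "b\tc\t0.3",
               "a\ta\t0.8", "a\tb\t0.9"), tmp)
  g <- read_edge_list(tmp)
  expect_equal(igraph::ecount(g), 2)   # self-loop and duplicate removed
  g2 <- read_edge_list(tmp, min_weight = 0.4)
  expect_equal(igraph::ecount(g2), 1)  # STRING-style confidence filter

  gmt <- tempfile(fileext = ".gmt")
  writeLines(c("set1\tdesc\tA\tB\tC", "set2\tdesc\tB\tD"), gmt)
  sets <- read_gmt(gmt)
  expect_equal(sets$set1, c("A", "B", "C"))
  writeLines("broken_line_no_genes", gmt)
  expect_error(read_gmt(gmt), "malformed GMT line 1")
})
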