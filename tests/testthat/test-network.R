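test_that("build_graph keeps only significant edges and all nodes", {
  # two columns that are identical permutations (rho = 1, exact p = 2/8!)
  # and one independent noise column
  set.seed(4)
  base <- sample(1:8)
  noise <- c(2.3, -1.1, 0.4, 1.9, -0.7, 0.2, -1.5, 0.8)
  d <- data.frame(P1 = base, P2 = base * 2 + 5, P3 = noise)
  # confirm the noise pairs are non-significant by enumeration first
  expect_gt(spearman_test(d$P1, d$P3, method = "exact_perm")$p_value, 0.05)
  expect_gt(spearman_test(d$P2, d$P3, method = "exact_perm")$p_value, 0.05)
  g <- build_graph(d, alpha = 0.05, method = "exact_perm")
  expect_equal(nrow(g$edges), 1)
  expect_setequal(c(g$edges$from, g$edges$to), c("P1", "P2"))
  expect_equal(g$edges$p, 2 / factorial(8))
  expect_equal(g$nodes, c("P1", "P2", "P3"))
})

test_that("constant columns give no incident edges but stay as nodes", {
  set.seed(9)
  d <- data.frame(A = rnorm(8), B = rnorm(8), SH = rep(0, 8))
  d$B <- d$A + rnorm(8, 0, 1e-3)   # strongly correlated pair
  g <- build_graph(d, alpha = 0.05)
  expect_true("SH" %in% g$nodes)
  expect_false(any(g$edges$from == "SH" | g$edges$to == "SH"))
  deg <- degree_centrality(g)
  expect_equal(unname(deg["SH"]), 0L)
})

test_that("edge set shrinks to empty as alpha shrinks, grows monotonically", {
  set.seed(12)
  d <- as.data.frame(matrix(rnorm(8 * 6), nrow = 8))
  d$V2 <- d$V1 + rnorm(8, 0, 0.1)
  alphas <- c(1e-9, 0.01, 0.05, 0.2, 1)
  sizes <- vapply(alphas, function(a)
    nrow(build_graph(d, alpha = a)$edges), numeric(1))
  expect_equal(sizes[1], 0)   # smallest exact p is 2/8! > 1e-9
  expect_true(all(diff(sizes) >= 0))
  expect_equal(sizes[length(sizes)], choose(6, 2))  # alpha = 1 keeps all pairs
})

test_that("edge set is independent of column order", {
  set.seed(3)
  d <- as.data.frame(matrix(rnorm(10 * 6), nrow = 10))
  d$V5 <- d$V4 * 2 + rnorm(10, 0, 0.2)
  g1 <- build_graph(d, alpha = 0.10)
  g2 <- build_graph(d[, sample(ncol(d))], alpha = 0.10)
  key <- function(g) sort(paste(pmin(g$edges$from, g$edges$to),
                                pmax(g$edges$from, g$edges$to)))
  expect_identical(key(g1), key(g2))
})

test_that("degree centrality is the incident-edge count", {
  tri <- correlation_graph(c("A", "B", "C"),
                           data.frame(from = c("A", "B", "A"),
                                      to = c("B", "C", "C"), rho = 1))
  expect_equal(unname(degree_centrality(tri)), c(2L, 2L, 2L))
  g <- correlation_graph(c("A", "B", "C", "D"),
                         data.frame(from = "A", to = "B", rho = 0.5))
  d <- degree_centrality(g)
  expect_equal(unname(d), c(1L, 1L, 0L, 0L))
  # handshake identity on random graphs
  set.seed(20)
  for (i in 1:10) {
    rg <- random_graph(sample(5:15, 1))
    expect_equal(sum(degree_centrality(rg)), 2 * nrow(rg$edges))
  }
})

test_that("pagerank reproduces closed-form solutions", {
  tri <- correlation_graph(c("A", "B", "C"),
                           data.frame(from = c("A", "B", "A"),
                                      to = c("B", "C", "C"), rho = 0.7))
  expect_equal(unname(pagerank(tri)), rep(1 / 3, 3), tolerance = 1e-8)
  # path A-B-C, unit weights: solution of x = 0.05 + 0.425 y, y = 0.05 + 1.7 x
  path <- correlation_graph(c("A", "B", "C"),
                            data.frame(from = c("A", "B"),
                                       to = c("B", "C"), rho = 1))
  pr <- pagerank(path, damping = 0.85)
  expect_equal(unname(pr), c(0.256757, 0.486486, 0.256757),
               tolerance = 1e-5)
  expect_equal(sum(pr), 1, tolerance = 1e-9)
})

test_that("pagerank is the stationary distribution of the damped walk", {
  set.seed(33)
  for (i in 1:15) {
    rg <- random_graph(sample(4:20, 1))
    pr <- pagerank(rg, tol = 1e-11)
    M <- transition_matrix(rg, damping = 0.85)
    residual <- sum(abs(as.numeric(crossprod(M, pr)) - pr))
    expect_lt(residual, 10 * 1e-11)
    expect_equal(sum(pr), 1, tolerance = 1e-9)
    expect_true(all(pr > 0))
  }
})

test_that("pagerank agrees with the igraph reference implementation", {
  set.seed(54)
  for (i in 1:8) {
    rg <- random_graph(sample(5:15, 1))
    pr <- pagerank(rg, tol = 1e-12)
    g <- igraph::graph_from_data_frame(
      rg$edges[, c("from", "to")], directed = FALSE,
      vertices = data.frame(name = rg$nodes))
    ref <- igraph::page_rank(g, damping = 0.85,
                             weights = rg$edges$weight)$vector
    expect_equal(unname(pr[rg$nodes]), unname(ref[rg$nodes]),
                 tolerance = 1e-6)
  }
})

test_that("pagerank splits mass equally across identical components and handles dangling nodes", {
  g <- correlation_graph(c("A", "B", "C", "D"),
                         data.frame(from = c("A", "C"), to = c("B", "D"),
                                    rho = c(0.9, 0.9)))
  pr <- pagerank(g)
  expect_equal(sum(pr[c("A", "B")]), 0.5, tolerance = 1e-8)
  expect_equal(unname(pr["A"]), unname(pr["C"]), tolerance = 1e-10)
  # isolated nodes keep positive mass
  g2 <- correlation_graph(c("A", "B", "Z"),
                          data.frame(from = "A", to = "B", rho = 1))
  expect_true(pagerank(g2)[["Z"]] > 0)
  # cycle (vertex-transitive): uniform masses, agreeing with degree ranking
  cyc <- correlation_graph(LETTERS[1:6],
                           data.frame(from = LETTERS[1:6],
                                      to = LETTERS[c(2:6, 1)], rho = 1))
  expect_equal(unname(pagerank(cyc)), rep(1 / 6, 6), tolerance = 1e-8)
})

test_that("pagerank reports non-convergence", {
  path <- correlation_graph(c("A", "B", "C"),
                            data.frame(from = c("A", "B"),
                                       to = c("B", "C"), rho = 1))
  expect_error(pagerank(path, tol = 1e-15, max_iter = 2L), "converge")
})

test_that("top-k ranking respects ties at and above the cut", {
  v <- c(A = 5, B = 5, C = 4, D = 3, E = 3, F = 2, G = 1)
  rt <- top_k_with_ties(v, k = 5)
  expect_equal(sort(rt$node[rt$in_top_k]), c("A", "B", "C", "D", "E"))
  expect_equal(rt$rank, c(1, 1, 3, 4, 4, 6, 7))
  # tie at the cut value extends the set
  v2 <- c(A = 5, B = 5, C = 4, D = 3, E = 3, F = 3, G = 1)
  rt2 <- top_k_with_ties(v2, k = 5)
  expect_equal(sum(rt2$in_top_k), 6)
  expect_true("F" %in% rt2$node[rt2$in_top_k])
  # saturation
  expect_true(all(top_k_with_ties(v, k = 100)$in_top_k))
  # real-valued metrics tie within relative tolerance
  v3 <- c(A = 0.5, B = 0.5 - 1e-12, C = 0.3, D = 0.2, E = 0.1, F = 0.05)
  rt3 <- top_k_with_ties(v3, k = 1)
  expect_equal(sum(rt3$in_top_k), 2)
  expect_equal(rt3$rank[1:2], c(1, 1))
})

test_that("default top-k cut is 10% of the node count", {
  expect_equal(default_top_k(52), 5)
  expect_equal(default_top_k(10), 1)
  expect_equal(default_top_k(4), 1)
})

test_that("graphs export to GraphML, GEXF and CSV with attributes intact", {
  set.seed(77)
  ds <- simulate_cohort(sim_config(n_athletes = 6, seed = 77))
  g <- build_graph(ds$CON, alpha = 0.05, scenario = "CON")
  expect_gt(nrow(g$edges), 0)

  p_gml <- withr::local_tempfile(fileext = ".graphml")
  write_graphml(g, p_gml)
  back <- igraph::read_graph(p_gml, format = "graphml")
  expect_equal(igraph::vcount(back), 52)
  expect_equal(igraph::ecount(back), nrow(g$edges))
  expect_true(all(c("category", "degree", "pagerank") %in%
                    igraph::vertex_attr_names(back)))
  expect_true(all(c("rho", "p", "weight", "sign") %in%
                    igraph::edge_attr_names(back)))

  p_gexf <- withr::local_tempfile(fileext = ".gexf")
  write_gexf(g, p_gexf)
  doc <- xml2::read_xml(p_gexf)
  ns <- xml2::xml_ns(doc)
  expect_equal(length(xml2::xml_find_all(doc, "//d1:node", ns)), 52)
  expect_equal(length(xml2::xml_find_all(doc, "//d1:edge", ns)),
               nrow(g$edges))

  p_csv <- withr::local_tempfile(fileext = ".csv")
  write_edge_csv(g, p_csv)
  ed <- utils::read.csv(p_csv)
  expect_equal(nrow(ed), nrow(g$edges))
  expect_equal(names(ed), c("source", "target", "rho", "p", "weight", "sign"))
})
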