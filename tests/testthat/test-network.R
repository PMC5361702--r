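test_that("correlation network finds duplicated features and matches cor()", {
  set.seed(103)
  m <- matrix(stats::rlnorm(6 * 5, 5), 5, 6,
              dimnames = list(paste0("F", 1:5), paste0("S", 1:6)))
  m[2, ] <- m[1, ] * 2   # perfectly correlated pair
  g <- correlation_network(peak_table(m), q_max = 0.05, min_overlap = 3)
  e <- graph_edges(g)
  pair <- e[(e$from == "F1" & e$to == "F2") |
              (e$from == "F2" & e$to == "F1"), ]
  expect_equal(nrow(pair), 1)
  expect_equal(pair$r, 1)

  # r values equal the brute-force formula for every tested pair
  tests <- graph_tests(g)
  for (i in seq_len(nrow(tests))) {
    x <- m[tests$from[i], ]; y <- m[tests$to[i], ]
    expect_equal(tests$r[i],
                 sum((x - mean(x)) * (y - mean(y))) /
                   sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2)))
  }

  # constant feature skipped with a warning
  m2 <- m; m2[3, ] <- 4
  expect_warning(correlation_network(peak_table(m2), min_overlap = 3),
                 "constant")
})

test_that("independent features yield almost no edges", {
  edge_frac <- vapply(1:3, function(s) {
    set.seed(110 + s)
    m <- matrix(stats::rnorm(30 * 20, 10), 30, 20,
                dimnames = list(paste0("F", 1:30), paste0("S", 1:20)))
    g <- correlation_network(peak_table(m), q_max = 0.05)
    igraph::ecount(g$graph) / choose(30, 2)
  }, numeric(1))
  expect_lte(mean(edge_frac), 0.01)
})

test_that("Fisher z statistics match the worked value and are antisymmetric", {
  # group A correlation exactly 0.9, group B exactly 0, n = 40 each
  pa <- exact_cor_pair(40, 0.9, seed = 1)
  pb <- exact_cor_pair(40, 0.0, seed = 2)
  m <- rbind(F1 = c(pa$x, pb$x), F2 = c(pa$y, pb$y),
             F3 = stats::rnorm(80))
  m <- m - min(m) + 1
  colnames(m) <- paste0("S", 1:80)
  meta <- sample_meta(paste0("S", 1:80), "1",
                      rep(c("A", "B"), each = 40), 1:80)
  g <- differential_correlation(peak_table(m), meta, "A", "B", q_max = 1)
  t12 <- graph_tests(g)
  row <- t12[t12$from == "F1" & t12$to == "F2", ]
  expect_equal(row$r_a, 0.9, tolerance = 1e-10)
  expect_equal(row$r_b, 0.0, tolerance = 1e-10)
  z_hand <- (atanh(0.9) - atanh(0)) / sqrt(1 / 37 + 1 / 37)
  expect_equal(row$z, z_hand, tolerance = 1e-8)
  expect_equal(round(z_hand, 2), 6.33)

  # swapping groups negates Z, leaves p and q unchanged
  g2 <- differential_correlation(peak_table(m), meta, "B", "A", q_max = 1)
  t21 <- graph_tests(g2)
  expect_equal(t21$z, -t12$z)
  expect_equal(t21$p, t12$p)
  expect_equal(t21$q, t12$q)
})

test_that("identical groups give Z = 0 and no edges", {
  set.seed(113)
  half <- matrix(stats::rnorm(5 * 10, 10), 5, 10)
  m <- cbind(half, half)
  dimnames(m) <- list(paste0("F", 1:5), paste0("S", 1:20))
  meta <- sample_meta(paste0("S", 1:20), "1",
                      rep(c("A", "B"), each = 10), 1:20)
  g <- differential_correlation(peak_table(m), meta, "A", "B")
  expect_true(all(graph_tests(g)$z == 0))
  expect_true(all(graph_tests(g)$p == 1))
  expect_equal(igraph::ecount(g$graph), 0)
})

test_that("centralities follow the path-graph hand computation", {
  g <- correlation_graph(data.frame(from = c("a", "b"), to = c("b", "c")),
                         nodes = c("a", "b", "c", "iso"))
  g <- graph_centralities(g)
  node <- tidy(g)
  expect_equal(node$degree[node$feature_id == "b"], 2)
  expect_equal(node$betweenness[node$feature_id == "b"], 1)
  expect_equal(node$closeness[node$feature_id == "iso"], 0)
  # closeness of b: 2 reachable at distance 1 each -> 2/2 = 1
  expect_equal(node$closeness[node$feature_id == "b"], 1)
  expect_equal(node$closeness[node$feature_id == "a"], 2 / 3)
})

test_that("fast-greedy communities split the two-clique fixture at Q = 0.42308", {
  g <- detect_communities(correlation_graph(two_clique_edges()))
  node <- tidy(g)
  expect_equal(length(unique(node$community)), 2)
  a_comm <- unique(node$community[grepl("^a", node$feature_id)])
  b_comm <- unique(node$community[grepl("^b", node$feature_id)])
  expect_equal(length(a_comm), 1)
  expect_equal(length(b_comm), 1)
  expect_false(a_comm == b_comm)
  expect_equal(g$modularity, 2 * (6 / 13 - (13 / 26)^2), tolerance = 1e-10)
  expect_equal(round(g$modularity, 5), 0.42308)

  # partition modularity equals the direct formula recomputation
  memb <- stats::setNames(node$community, node$feature_id)
  expect_equal(g$modularity, modularity_direct(two_clique_edges(), memb),
               tolerance = 1e-12)

  # single clique collapses to one community
  cl <- utils::combn(paste0("x", 1:5), 2)
  g1 <- detect_communities(correlation_graph(
    data.frame(from = cl[1, ], to = cl[2, ])))
  expect_equal(length(unique(tidy(g1)$community)), 1)

  # edgeless graph: singleton communities, Q = 0
  g0 <- detect_communities(correlation_graph(
    data.frame(from = character(0), to = character(0)),
    nodes = c("n1", "n2")))
  expect_equal(length(unique(tidy(g0)$community)), 2)
  expect_equal(g0$modularity, 0)
})

test_that("giant component statistics behave on the two-clique fixture", {
  g <- correlation_graph(two_clique_edges())
  expect_equal(glance(g)$giant_component_frac, 1.0)
  no_bridge <- two_clique_edges()
  no_bridge <- no_bridge[!(no_bridge$from == "a1" & no_bridge$to == "b1"), ]
  g2 <- correlation_graph(no_bridge, nodes = c(paste0("a", 1:4),
                                               paste0("b", 1:4)))
  expect_equal(glance(g2)$n_components, 2)
  expect_equal(glance(g2)$giant_component_frac, 0.5)
})

test_that("GML and Pajek exports round-trip the node and edge sets", {
  dir <- withr::local_tempdir()
  g <- detect_communities(graph_centralities(
    correlation_graph(two_clique_edges())))
  for (fmt in c("gml", "pajek")) {
    path <- file.path(dir, paste0("net.", fmt))
    export_graph(g, path, fmt)
    back <- import_graph(path, fmt)
    expect_setequal(igraph::V(back$graph)$name, tidy(g)$feature_id)
    expect_equal(igraph::ecount(back$graph), igraph::ecount(g$graph))
  }
  # Pajek vertex-count header
  lines <- readLines(file.path(dir, "net.pajek"))
  expect_match(lines[1], "\\*Vertices +8", ignore.case = TRUE)
  # GML carries the community attribute
  expect_true(any(grepl("community", readLines(file.path(dir, "net.gml")))))
  # empty graph still exports a parseable document
  g0 <- correlation_graph(data.frame(from = character(0), to = character(0)))
  export_graph(g0, file.path(dir, "empty.gml"), "gml")
  expect_equal(igraph::vcount(
    import_graph(file.path(dir, "empty.gml"), "gml")$graph), 0)
  expect_error(export_graph(g, file.path(dir, "x"), "dot"),
               "should be one of")
})
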