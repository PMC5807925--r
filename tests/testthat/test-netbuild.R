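# Hand-built edge tables for four methods over a fixed pair universe.
mk_edges <- function(method, p, dir) {
  pairs <- tibble::tibble(
    otu_a = c("a", "a", "a", "b", "b", "c"),
    otu_b = c("b", "c", "d", "c", "d", "d"))
  tibble::tibble(pairs, method = method, statistic = dir * 0.5,
                 direction = as.integer(dir), p_raw = p, p_adjusted = p)
}

test_that("directional intersection applies the matched-direction strict-p rule", {
  #              ab     ac     ad     bc     bd     cd
  p1 <- c(0.005, 0.005, 0.500, 0.005, 0.009, 0.005)
  p2 <- c(0.005, 0.005, 0.005, 0.005, 0.009, 0.005)
  p3 <- c(0.005, 0.010, 0.005, 0.005, 0.009, 0.005)  # ac at exactly 0.01
  p4 <- c(0.005, 0.005, 0.005, 0.005, 0.009, 0.005)
  d1 <- c(1, 1, 1, -1, 1, 1)
  d2 <- c(1, 1, 1, -1, 1, 1)
  d3 <- c(1, 1, 1, -1, 1, 1)
  d4 <- c(1, 1, 1, -1, 1, -1)  # cd direction conflict
  tables <- list(m1 = mk_edges("m1", p1, d1), m2 = mk_edges("m2", p2, d2),
                 m3 = mk_edges("m3", p3, d3), m4 = mk_edges("m4", p4, d4))
  net <- intersect_edge_tables(tables, 0.01)
  # by hand: ab kept (+), ac dropped (p3 not strictly < 0.01), ad dropped
  # (p1 = 0.5), bc kept (-), bd kept (+), cd dropped (direction conflict)
  expect_equal(nrow(net), 3)
  expect_equal(net$sign[net$otu_a == "a" & net$otu_b == "b"], 1L)
  expect_equal(net$sign[net$otu_a == "b" & net$otu_b == "c"], -1L)
  expect_equal(net$sign[net$otu_a == "b" & net$otu_b == "d"], 1L)
  expect_error(intersect_edge_tables(tables[1], 0.01), "at least two")
})

test_that("the threshold sweep is monotone with a brute-force recount", {
  tables <- list(
    m1 = mk_edges("m1", c(0.04, 0.005, 0.0005, 0.04, 0.9, 1e-5), rep(1, 6)),
    m2 = mk_edges("m2", c(0.03, 0.004, 0.0004, 0.03, 0.9, 1e-5), rep(1, 6)),
    m3 = mk_edges("m3", c(0.02, 0.003, 0.0003, 0.02, 0.9, 1e-5), rep(1, 6)),
    m4 = mk_edges("m4", c(0.01, 0.002, 0.0002, 0.01, 0.9, 1e-5), rep(1, 6)))
  expect_length(default_thresholds(), 8)
  sw <- threshold_sweep(tables, c(0.05, 0.01, 1e-3, 1e-4))
  expect_true(all(diff(sw$n_edges) <= 0))
  # brute-force recount per threshold: max p across methods must be < th
  pmax4 <- pmax(tables$m1$p_raw, tables$m2$p_raw, tables$m3$p_raw,
                tables$m4$p_raw)
  for (i in seq_len(nrow(sw))) {
    expect_equal(sw$n_edges[i], sum(pmax4 < sw$threshold[i]))
  }
  expect_true(is.na(sw$r_squared[nrow(sw)]) || sw$n_edges[nrow(sw)] > 0)
})

test_that("scale-free fit matches closed-form cases", {
  # star S10: two degree classes -> two-point regression by hand
  fit <- scale_free_fit(star10(), n_breaks = 10)
  slope_hand <- (log10(1 / 11) - log10(10 / 11)) / (log10(10) - log10(1))
  expect_equal(fit$slope, slope_hand, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1)
  # k-regular graph: degenerate sentinel
  expect_true(is.na(scale_free_fit(two_k4s())$r_squared))
  # constructed power law with exact binned points: p(k) ~ k^-2 on degrees
  # that each fall in their own bin
  k <- c(1, 2, 4, 8)
  nk <- c(6400, 1600, 400, 100)
  fit2 <- scale_free_fit(rep(k, nk), n_breaks = 8)
  expect_equal(fit2$slope, -2, tolerance = 1e-9)
  expect_equal(fit2$r_squared, 1, tolerance = 1e-9)
})

test_that("network summaries agree with a brute-force BFS oracle", {
  k4 <- new_network(tibble::tibble(
    otu_a = c("a", "a", "a", "b", "b", "c"),
    otu_b = c("b", "c", "d", "c", "d", "d"), sign = 1L))
  s <- network_summary(k4)
  expect_equal(s$n_nodes, 4)
  expect_equal(s$n_edges, 6)
  expect_equal(s$graph_density, 1)
  expect_equal(s$mean_path_length, 1)
  expect_equal(s$mean_clustering_coefficient, 1)

  p4 <- new_network(tibble::tibble(otu_a = c("a", "b", "c"),
                                   otu_b = c("b", "c", "d"), sign = 1L))
  expect_equal(network_summary(p4)$mean_degree, 1.5)

  # 7-node toy (two components, a triangle tail + an edge) vs a BFS oracle
  toy <- new_network(tibble::tibble(
    otu_a = c("a", "a", "b", "c", "d", "f"),
    otu_b = c("b", "c", "c", "d", "e", "g"), sign = 1L))
  s <- network_summary(toy)
  nodes <- network_nodes(toy)
  A <- matrix(0, 7, 7, dimnames = list(nodes, nodes))
  for (i in seq_len(nrow(toy))) {
    A[toy$otu_a[i], toy$otu_b[i]] <- A[toy$otu_b[i], toy$otu_a[i]] <- 1
  }
  bfs_dist <- function(src) {
    d <- rep(Inf, 7); names(d) <- nodes; d[src] <- 0
    q <- src
    while (length(q)) {
      u <- q[1]; q <- q[-1]
      for (v in nodes[A[u, ] == 1]) {
        if (d[v] == Inf) { d[v] <- d[u] + 1; q <- c(q, v) }
      }
    }
    d
  }
  dists <- t(vapply(nodes, bfs_dist, numeric(7)))
  finite <- dists[upper.tri(dists)][is.finite(dists[upper.tri(dists)])]
  expect_equal(s$mean_path_length, mean(finite))
  local_cc <- vapply(nodes, function(u) {
    nb <- nodes[A[u, ] == 1]
    if (length(nb) < 2) return(0)
    sum(A[nb, nb]) / 2 / choose(length(nb), 2)
  }, numeric(1))
  expect_equal(s$mean_clustering_coefficient, mean(local_cc))
  expect_equal(s$mean_degree, 2 * 6 / 7)
  expect_equal(s$graph_density, 6 / choose(7, 2))
})

test_that("negative-edge stripping filters signs and drops isolated nodes", {
  mixed <- new_network(tibble::tibble(
    otu_a = c("a", "b", "c", "e"),
    otu_b = c("b", "c", "d", "f"),
    sign = c(1L, -1L, 1L, -1L)))
  out <- strip_negative_edges(mixed)
  expect_equal(nrow(out), 2)
  expect_setequal(network_nodes(out), c("a", "b", "c", "d"))
  expect_equal(attr(out, "fraction_removed"), 0.5)
  allpos <- new_network(tibble::tibble(otu_a = "a", otu_b = "b", sign = 1L))
  expect_equal(nrow(strip_negative_edges(allpos)), 1)
  allneg <- new_network(tibble::tibble(otu_a = "a", otu_b = "b", sign = -1L))
  expect_equal(nrow(strip_negative_edges(allneg)), 0)
})
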