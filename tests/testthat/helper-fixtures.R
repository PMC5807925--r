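# Fixtures built in code, shared across test files.

# Tiny count table: 3 samples x 4 OTUs, fully known values.
toy_counts <- function() {
  as_count_table(matrix(
    c(5L, 0L, 3L, 2L,
      1L, 4L, 0L, 5L,
      0L, 0L, 7L, 3L),
    nrow = 3, byrow = TRUE,
    dimnames = list(c("s1", "s2", "s3"), c("o1", "o2", "o3", "o4"))))
}

# The 5x5 table used to enumerate the quality filters by hand:
# depths: s1 = 12000, s2 = 9999, s3 = 15000, s4 = 10000, s5 = 8000
# after the depth filter (>= 10000) samples s1, s3, s4 remain; occupancy
# among those: o1 in 3, o2 in 1, o3 in 2, o4 in 0, o5 in 2.
filter_toy <- function() {
  m <- rbind(
    s1 = c(o1 = 6000L, o2 = 0L,    o3 = 3000L, o4 = 0L, o5 = 3000L),
    s2 = c(o1 = 9999L, o2 = 0L,    o3 = 0L,    o4 = 0L, o5 = 0L),
    s3 = c(o1 = 5000L, o2 = 5000L, o3 = 5000L, o4 = 0L, o5 = 0L),
    s4 = c(o1 = 4000L, o2 = 0L,    o3 = 0L,    o4 = 0L, o5 = 6000L),
    s5 = c(o1 = 0L,    o2 = 4000L, o3 = 0L,    o4 = 4000L, o5 = 0L))
  as_count_table(m)
}

# Network of two disjoint K4 cliques (a1..a4, b1..b4).
two_k4s <- function() {
  cl <- function(p) {
    ids <- paste0(p, 1:4)
    idx <- combn(4, 2)
    tibble::tibble(otu_a = ids[idx[1, ]], otu_b = ids[idx[2, ]], sign = 1L)
  }
  new_network(dplyr::bind_rows(cl("a"), cl("b")))
}

# Network of two disjoint K3 triangles.
two_k3s <- function() {
  new_network(tibble::tibble(
    otu_a = c("a1", "a1", "a2", "b1", "b1", "b2"),
    otu_b = c("a2", "a3", "a3", "b2", "b3", "b3"),
    sign = 1L))
}

# Star S10: hub h connected to 10 leaves.
star10 <- function() {
  new_network(tibble::tibble(otu_a = "h", otu_b = paste0("l", 1:10),
                             sign = 1L))
}

# Partition tibble from a plain named vector.
part_of <- function(v) new_partition(v)

# All set partitions of n elements as a list of integer assignment vectors
# (restricted growth strings). Used as the exhaustive oracle driver.
all_partitions <- function(n) {
  out <- list()
  rec <- function(a, k) {
    i <- length(a) + 1
    if (i > n) {
      out[[length(out) + 1]] <<- a
      return(invisible())
    }
    for (v in seq_len(k + 1)) rec(c(a, v), max(k, v))
  }
  rec(integer(0), 0L)
  out
}

# Independent brute-force modularity oracle: the full double sum
# (1/2m) * sum_ij (A_ij - gamma k_i k_j / 2m) delta(c_i, c_j).
brute_modularity <- function(net, assignment, gamma) {
  nodes <- network_nodes(net)
  A <- matrix(0, length(nodes), length(nodes),
              dimnames = list(nodes, nodes))
  for (r in seq_len(nrow(net))) {
    A[net$otu_a[r], net$otu_b[r]] <- A[net$otu_a[r], net$otu_b[r]] + 1
    A[net$otu_b[r], net$otu_a[r]] <- A[net$otu_b[r], net$otu_a[r]] + 1
  }
  k <- rowSums(A)
  m2 <- sum(k)
  cc <- assignment[nodes]
  q <- 0
  for (i in seq_along(nodes)) {
    for (j in seq_along(nodes)) {
      if (cc[i] == cc[j]) q <- q + A[i, j] - gamma * k[i] * k[j] / m2
    }
  }
  unname(q / m2)
}

# Random partition of given node ids (uniform community count 1..k_max).
random_partition <- function(ids, k_max = 5, seed = 1) {
  withr::with_seed(seed, {
    k <- sample(k_max, 1)
    new_partition(stats::setNames(sample(k, length(ids), replace = TRUE), ids))
  })
}
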