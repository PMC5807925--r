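# Community detection: generalised modularity, Louvain, degree-matched
# randomisation, and the resolution (gamma) sweep used to pick a gamma that
# gives both stable and significant communities.

#' Construct a partition
#'
#' A partition assigns every network node to exactly one community. Ids are
#' relabelled to be contiguous from 1 (largest community first for
#' determinism).
#'
#' @param assignment A named integer/character vector (names = OTU ids) or a
#'   data frame with `otu_id` and `community_id`.
#' @param gamma The resolution the partition was found at.
#' @param modularity Q of the partition at that gamma.
#' @return A `coocc_partition` tibble (`otu_id`, `community_id`).
#' @export
new_partition <- function(assignment, gamma = NA_real_, modularity = NA_real_) {
  if (is.data.frame(assignment)) {
    stopifnot(all(c("otu_id", "community_id") %in% names(assignment)))
    v <- setNames(assignment$community_id, assignment$otu_id)
  } else {
    v <- assignment
  }
  if (is.null(names(v)) || anyDuplicated(names(v))) {
    abort("assignment must be named by unique node ids")
  }
  sizes <- sort(table(v), decreasing = TRUE)
  relabel <- setNames(seq_along(sizes), names(sizes))
  out <- tibble(otu_id = names(v),
                community_id = unname(relabel[as.character(v)]))
  out <- arrange(out, .data$otu_id)
  structure(out, gamma = gamma, modularity = modularity,
            class = c("coocc_partition", class(tibble())))
}

partition_vector <- function(part) setNames(part$community_id, part$otu_id)

#' Generalised modularity Q at resolution gamma
#'
#' `Q = (1/2m) * sum_ij (A_ij - gamma * k_i k_j / 2m) * delta(c_i, c_j)`
#' on the unweighted adjacency, equivalently
#' `sum_c (m_c / m - gamma * (d_c / 2m)^2)` with `m_c` the edges inside
#' community c and `d_c` its total degree.
#'
#' @param net An unsigned `coocc_network` (positive edges only).
#' @param part A `coocc_partition` covering the network's nodes.
#' @param gamma Resolution parameter (default 1).
#' @return Q, a scalar in \[-1, 1\].
#' @export
modularity_q <- function(net, part, gamma = 1) {
  if (nrow(net) == 0) abort("modularity is undefined on an empty network")
  if (any(net$sign < 0)) abort("network must be unsigned; strip_negative_edges() first")
  cm <- partition_vector(part)
  nodes <- network_nodes(net)
  if (!all(nodes %in% names(cm))) abort("partition does not cover all network nodes")
  m <- nrow(net)
  ca <- cm[net$otu_a]; cb <- cm[net$otu_b]
  within <- tapply(rep(1, m)[ca == cb], ca[ca == cb], sum)
  deg <- table(factor(c(net$otu_a, net$otu_b), levels = nodes))
  dc <- tapply(as.numeric(deg), cm[nodes], sum)
  mc <- setNames(rep(0, length(dc)), names(dc))
  mc[names(within)] <- within
  sum(mc / m - gamma * (dc / (2 * m))^2)
}

#' Louvain community detection at a resolution
#'
#' Greedy two-phase modularity maximisation (local moves, then graph
#' aggregation, repeated to convergence) with a seeded random node order.
#'
#' @param net A non-empty unsigned `coocc_network`.
#' @param gamma Resolution (default 1).
#' @param seed Integer seed; the same seed gives the identical partition.
#' @return A `coocc_partition` with `gamma` and `modularity` attributes.
#' @export
louvain <- function(net, gamma = 1, seed = 1) {
  if (nrow(net) == 0) abort("cannot detect communities in an empty network")
  if (any(net$sign < 0)) abort("network must be unsigned; strip_negative_edges() first")
  g <- as_igraph_network(net)
  memb <- with_seed(seed,
    igraph::membership(igraph::cluster_louvain(g, resolution = gamma)))
  part <- new_partition(setNames(as.integer(memb), names(memb)), gamma = gamma)
  attr(part, "modularity") <- modularity_q(net, part, gamma)
  part
}

#' Random simple graph with a fixed degree sequence
#'
#' Builds a deterministic graphical realisation (Havel-Hakimi) and then
#' randomises it with seeded double-edge swaps that preserve every node's
#' degree while keeping the graph simple.
#'
#' @param degrees Integer degree sequence (must be graphical).
#' @param seed Integer seed.
#' @param n_swaps Number of attempted swaps (default `10 *` edge count).
#' @return A `coocc_network` over nodes `n1..nN` with the exact degree
#'   sequence requested.
#' @export
random_graph_from_degree_sequence <- function(degrees, seed = 1, n_swaps = NULL) {
  degrees <- as.integer(degrees)
  if (!igraph::is_graphical(degrees)) abort("degree sequence is not graphical")
  g <- igraph::realize_degseq(degrees)
  n_swaps <- n_swaps %||% (10L * igraph::ecount(g))
  if (igraph::ecount(g) > 0 && n_swaps > 0) {
    g <- with_seed(seed, igraph::rewire(g, igraph::keeping_degseq(niter = n_swaps)))
  }
  el <- igraph::as_edgelist(g, names = FALSE)
  ids <- paste0("n", seq_along(degrees))
  # keep zero-degree entries out: the network convention has no isolated nodes
  new_network(tibble(otu_a = ids[el[, 1]], otu_b = ids[el[, 2]],
                     sign = 1L))
}

# Degree sequence of a network (named).
network_degrees <- function(net) {
  nodes <- network_nodes(net)
  as.integer(table(factor(c(net$otu_a, net$otu_b), levels = nodes)))
}

#' Resolution sweep: stability and significance per gamma
#'
#' At each gamma, Louvain is run `n_runs` times on the real network;
#' stability is the mean over run pairs of `1 - VI / ln N` (1 = identical
#' partitions every run). Significance compares the real runs' modularity
#' with one Louvain run on each of `n_random` degree-matched random graphs
#' (generated once per sweep by double-edge swaps).
#'
#' @param net A non-empty unsigned `coocc_network`.
#' @param gammas Resolutions to scan (default 0.1 to 1 in steps of 0.01).
#' @param n_runs Louvain runs per gamma on the real network (default 25).
#' @param n_random Degree-matched random graphs (default 100).
#' @param seed Integer seed.
#' @return A `gamma_sweep` tibble: `gamma`, `stability_mean`,
#'   `stability_sd`, `q_real_mean`, `q_real_sd`, `q_random_mean`,
#'   `q_random_sd`, `n_communities_mean`.
#' @export
gamma_sweep <- function(net, gammas = seq(0.1, 1, by = 0.01), n_runs = 25,
                        n_random = 100, seed = 1) {
  seeds <- derive_seeds(seed, 2)
  rg_seeds <- derive_seeds(seeds[1], n_random)
  degs <- network_degrees(net)
  randoms <- map(rg_seeds, ~ random_graph_from_degree_sequence(degs, seed = .x))
  run_seed_mat <- matrix(derive_seeds(seeds[2], length(gammas) * (n_runs + n_random)),
                         nrow = length(gammas))
  n_shared <- length(network_nodes(net))
  rows <- map(seq_along(gammas), function(gi) {
    gamma <- gammas[gi]
    s_real <- run_seed_mat[gi, seq_len(n_runs)]
    parts <- map(s_real, ~ louvain(net, gamma = gamma, seed = .x))
    qs <- map_dbl(parts, ~ attr(.x, "modularity"))
    pairs <- combn(n_runs, 2)
    sims <- map_dbl(seq_len(ncol(pairs)), function(j) {
      normalized_vi(parts[[pairs[1, j]]], parts[[pairs[2, j]]])$one_minus_nvi
    })
    s_rand <- run_seed_mat[gi, n_runs + seq_len(n_random)]
    q_rand <- map2_dbl(randoms, s_rand, function(rg, s) {
      attr(louvain(rg, gamma = gamma, seed = s), "modularity")
    })
    tibble(gamma = gamma,
           stability_mean = mean(sims), stability_sd = sd(sims),
           q_real_mean = mean(qs), q_real_sd = sd(qs),
           q_random_mean = mean(q_rand), q_random_sd = sd(q_rand),
           n_communities_mean = mean(map_dbl(parts, ~ max(.x$community_id))))
  })
  structure(list_rbind(rows), class = c("gamma_sweep", class(tibble())))
}

#' Final best-of-n partition at a chosen gamma
#'
#' Runs Louvain `n_runs` times and keeps the partition with the highest
#' modularity (ties broken by the earliest run).
#'
#' @param net A non-empty unsigned `coocc_network`.
#' @param gamma Resolution.
#' @param n_runs Number of runs (default 100).
#' @param seed Integer seed.
#' @return The best `coocc_partition`.
#' @export
final_partition <- function(net, gamma, n_runs = 100, seed = 1) {
  seeds <- derive_seeds(seed, n_runs)
  best <- NULL
  for (s in seeds) {
    p <- louvain(net, gamma = gamma, seed = s)
    if (is.null(best) || attr(p, "modularity") > attr(best, "modularity")) {
      best <- p
    }
  }
  best
}

#' @export
tidy.coocc_partition <- function(x, ...) as_tibble(x)

#' @export
glance.coocc_partition <- function(x, ...) {
  tibble(n_nodes = nrow(x), n_communities = max(x$community_id),
         gamma = attr(x, "gamma"), modularity = attr(x, "modularity"))
}

#' @export
print.coocc_partition <- function(x, ...) {
  cat("Partition of", nrow(x), "nodes into", max(x$community_id),
      "communities (gamma =", attr(x, "gamma"),
      ", Q =", round(attr(x, "modularity"), 4), ")\n")
  NextMethod()
}

#' Write a partition as TSV
#'
#' @param part A `coocc_partition`.
#' @param path Output path.
#' @export
write_partition <- function(part, path) {
  readr::write_tsv(as_tibble(part), path, progress = FALSE)
}
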