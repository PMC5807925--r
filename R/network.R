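# Ensemble networks: directional intersection of edge tables, the p-value
# threshold sweep, scale-free fit scoring, and network summaries.

#' Construct a co-occurrence network
#'
#' A network is a tibble of signed undirected edges (`otu_a`, `otu_b`,
#' `sign` in {+1, -1}) with `otu_a < otu_b`, no duplicates and no
#' self-loops. Nodes exist only through edges (an isolated OTU is not part
#' of the network), matching the convention of counting OTUs with at least
#' one edge.
#'
#' @param edges A data frame with `otu_a`, `otu_b`, `sign`.
#' @param p_threshold Optional provenance: the p cutoff that produced it.
#' @param methods Optional provenance: contributing method names.
#' @return A `coocc_network` tibble.
#' @export
new_network <- function(edges, p_threshold = NA_real_, methods = character()) {
  e <- as_tibble(edges)
  if (nrow(e) == 0) {
    e <- tibble(otu_a = character(), otu_b = character(), sign = integer())
  }
  stopifnot(all(c("otu_a", "otu_b", "sign") %in% names(e)))
  swap <- e$otu_a > e$otu_b
  tmp <- e$otu_a[swap]; e$otu_a[swap] <- e$otu_b[swap]; e$otu_b[swap] <- tmp
  if (any(e$otu_a == e$otu_b)) abort("self-loops are not allowed")
  if (anyDuplicated(pair_key(e$otu_a, e$otu_b))) abort("parallel edges are not allowed")
  if (!all(e$sign %in% c(-1L, 1L))) abort("edge signs must be +1 or -1")
  e$sign <- as.integer(e$sign)
  e <- arrange(e[, c("otu_a", "otu_b", "sign")], .data$otu_a, .data$otu_b)
  structure(e, p_threshold = p_threshold, methods = methods,
            class = c("coocc_network", class(tibble())))
}

#' Nodes of a network
#'
#' @param net A `coocc_network`.
#' @return Sorted character vector of OTU ids with at least one edge.
#' @export
network_nodes <- function(net) sort(unique(c(net$otu_a, net$otu_b)))

#' igraph view of a network
#'
#' @param net A `coocc_network`.
#' @return An undirected simple igraph graph with a `sign` edge attribute.
#' @export
as_igraph_network <- function(net) {
  igraph::graph_from_data_frame(
    data.frame(from = net$otu_a, to = net$otu_b, sign = net$sign),
    directed = FALSE)
}

#' Directional intersection of per-method edge tables
#'
#' An edge is retained when the pair is present in every table with the
#' same direction and an adjusted p-value strictly below `p_threshold` in
#' every method. Sentinel directions (0) never match.
#'
#' @param tables A named list of edge-table tibbles (one per method).
#' @param p_threshold The p cutoff (strict `<`).
#' @return A `coocc_network` with provenance attributes.
#' @export
intersect_edge_tables <- function(tables, p_threshold) {
  if (length(tables) < 2) abort("need at least two edge tables to intersect")
  if (is.null(names(tables)) || any(names(tables) == "")) {
    names(tables) <- map_chr(tables, ~ .x$method[1] %||% "unknown")
  }
  keyed <- map(tables, function(e) {
    validate_edge_table(e)
    e <- filter(e, .data$p_adjusted < p_threshold, .data$direction != 0L)
    tibble(key = pair_key(e$otu_a, e$otu_b), otu_a = e$otu_a, otu_b = e$otu_b,
           direction = e$direction)
  })
  common <- Reduce(intersect, map(keyed, "key"))
  if (length(common) == 0) {
    return(new_network(tibble(otu_a = character(), otu_b = character(),
                              sign = integer()),
                       p_threshold = p_threshold, methods = names(tables)))
  }
  dirs <- map(keyed, function(k) k$direction[match(common, k$key)])
  dmat <- do.call(cbind, dirs)
  agree <- apply(dmat, 1, function(x) length(unique(x)) == 1L)
  first <- keyed[[1]]
  sel <- match(common[agree], first$key)
  new_network(tibble(otu_a = first$otu_a[sel], otu_b = first$otu_b[sel],
                     sign = dmat[agree, 1]),
              p_threshold = p_threshold, methods = names(tables))
}

#' Default p-value threshold ladder
#'
#' 0.05 followed by powers of ten from 0.01 down to 1e-8.
#' @return Numeric vector of 8 thresholds, descending.
#' @export
default_thresholds <- function() c(0.05, 10^-(2:8))

#' Intersection networks across a p-value sweep
#'
#' Builds the directional intersection at each threshold (descending) and
#' scores each network's scale-free fit and summary statistics. Edge counts
#' are checked to be monotone non-increasing as the threshold tightens.
#'
#' @param tables A named list of edge-table tibbles.
#' @param thresholds Descending p thresholds (default [default_thresholds()]).
#' @param n_breaks Degree bins for [scale_free_fit()].
#' @return A `threshold_sweep` tibble: one row per threshold with network
#'   summary columns, `r_squared`, `slope`, and a `network` list-column.
#' @export
threshold_sweep <- function(tables, thresholds = default_thresholds(),
                            n_breaks = 10) {
  if (is.unsorted(rev(thresholds), strictly = TRUE)) {
    abort("thresholds must be sorted descending")
  }
  rows <- map(thresholds, function(th) {
    net <- intersect_edge_tables(tables, th)
    fit <- scale_free_fit(net, n_breaks = n_breaks)
    s <- network_summary(net)
    tibble(threshold = th, s, r_squared = fit$r_squared, slope = fit$slope,
           network = list(net))
  })
  out <- list_rbind(rows)
  if (is.unsorted(rev(out$n_edges))) {
    abort("internal error: edge counts not monotone across the sweep")
  }
  structure(out, class = c("threshold_sweep", class(tibble())))
}

#' Scale-free fit index of a degree distribution
#'
#' Node degrees are binned into `n_breaks` equal-width bins; for each
#' non-empty bin the mean degree and the fraction of nodes are computed, and
#' log10(fraction) is regressed on log10(mean degree). A genuine power law
#' p(k) ~ k^-2 yields R^2 near 1 and slope near -2.
#'
#' @param net A `coocc_network` (or an integer degree vector).
#' @param n_breaks Number of equal-width degree bins (default 10).
#' @return A one-row tibble: `r_squared`, `slope`, `n_breaks`. Degenerate
#'   inputs (empty network, a single distinct degree) give NA sentinels.
#' @export
scale_free_fit <- function(net, n_breaks = 10) {
  k <- if (inherits(net, "coocc_network")) {
    igraph::degree(as_igraph_network(net))
  } else {
    as.numeric(net)
  }
  sentinel <- tibble(r_squared = NA_real_, slope = NA_real_, n_breaks = n_breaks)
  if (length(k) == 0 || length(unique(k)) < 2) return(sentinel)
  breaks <- seq(min(k), max(k), length.out = n_breaks + 1)
  bin <- cut(k, breaks = breaks, include.lowest = TRUE)
  dk <- tapply(k, bin, mean)
  pk <- tapply(k, bin, length) / length(k)
  keep <- !is.na(dk) & dk > 0 & !is.na(pk) & pk > 0
  if (sum(keep) < 2) return(sentinel)
  fit <- lm(log10(pk[keep]) ~ log10(dk[keep]))
  # summary.lm warns on exact fits; constructed power-law fixtures are
  # legitimately exact
  r2 <- suppressWarnings(summary(fit)$r.squared)
  tibble(r_squared = r2, slope = unname(coef(fit)[2]), n_breaks = n_breaks)
}

#' Descriptive statistics of a network
#'
#' Density is edges over all possible pairs; mean path length averages
#' shortest paths over connected node pairs only; the clustering
#' coefficient is the mean local clustering with degree-0/1 nodes
#' contributing 0.
#'
#' @param net A `coocc_network`.
#' @return A one-row tibble: `n_nodes`, `n_edges`, `mean_degree`,
#'   `graph_density`, `mean_path_length`, `mean_clustering_coefficient`.
#' @export
network_summary <- function(net) {
  if (nrow(net) == 0) {
    return(tibble(n_nodes = 0L, n_edges = 0L, mean_degree = NA_real_,
                  graph_density = NA_real_, mean_path_length = NA_real_,
                  mean_clustering_coefficient = NA_real_))
  }
  g <- as_igraph_network(net)
  n <- igraph::vcount(g); e <- igraph::ecount(g)
  tibble(n_nodes = n, n_edges = e,
         mean_degree = 2 * e / n,
         graph_density = e / choose(n, 2),
         mean_path_length = igraph::mean_distance(g, unconnected = TRUE),
         mean_clustering_coefficient =
           mean(igraph::transitivity(g, type = "local", isolates = "zero")))
}

#' Remove negative edges
#'
#' Keeps only +1 edges; nodes left without any edge drop out of the
#' network. The fraction of edges removed is attached as attribute
#' `fraction_removed` and reported via a message when nonzero.
#'
#' @param net A `coocc_network`.
#' @return An unsigned (all +1) `coocc_network`.
#' @export
strip_negative_edges <- function(net) {
  frac <- if (nrow(net) == 0) 0 else mean(net$sign < 0)
  out <- new_network(filter(net, .data$sign > 0),
                     p_threshold = attr(net, "p_threshold"),
                     methods = attr(net, "methods"))
  attr(out, "fraction_removed") <- frac
  out
}

#' Write a network as a signed edge-list TSV
#'
#' @param net A `coocc_network`.
#' @param path Output path.
#' @export
write_network <- function(net, path) {
  readr::write_tsv(as_tibble(net), path, progress = FALSE)
}
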