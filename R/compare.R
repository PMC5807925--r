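# Cross-network comparison of community structure: normalised variation of
# information on shared nodes with a label-shuffle permutation null, and
# Jaccard-based mapping of individual communities into community-types.

# VI between two assignment vectors over the same nodes, natural logs.
vi_from_vectors <- function(a, b) {
  n <- length(a)
  tab <- table(a, b)
  p <- tab / n
  pa <- rowSums(p); pb <- colSums(p)
  ha <- -sum(pa[pa > 0] * log(pa[pa > 0]))
  hb <- -sum(pb[pb > 0] * log(pb[pb > 0]))
  nz <- p > 0
  mi <- sum(p[nz] * log(p[nz] / (outer(pa, pb)[nz])))
  max(ha + hb - 2 * mi, 0)
}

#' Normalised variation of information between two partitions
#'
#' Both partitions are restricted to their shared node set; VI =
#' H(a) + H(b) - 2 I(a; b) with natural logarithms, normalised by ln of the
#' shared node count so nVI is in \[0, 1\]. The similarity `1 - nVI` is 1
#' for identical segmentations and 0 for maximally different ones.
#'
#' @param a,b `coocc_partition` objects (or tibbles with `otu_id`,
#'   `community_id`); their node sets may differ.
#' @return A list: `vi`, `nvi`, `one_minus_nvi`, `shared_nodes`.
#' @export
normalized_vi <- function(a, b) {
  va <- partition_vector(a); vb <- partition_vector(b)
  shared <- intersect(names(va), names(vb))
  if (length(shared) < 2) abort("need at least 2 shared nodes to compare partitions")
  vi <- vi_from_vectors(va[shared], vb[shared])
  nvi <- vi / log(length(shared))
  nvi <- min(max(nvi, 0), 1)
  list(vi = vi, nvi = nvi, one_minus_nvi = 1 - nvi,
       shared_nodes = length(shared))
}

#' Permutation null for partition similarity
#'
#' Shuffles the node labels of both partitions (community size multisets
#' preserved) and recomputes `1 - nVI`, `n_permutations` times; reports the
#' observed similarity against the null mean, sd and maximum, plus an
#' empirical add-one p-value for the observed similarity.
#'
#' @param a,b `coocc_partition` objects.
#' @param n_permutations Number of shuffles (default 1000).
#' @param seed Integer seed.
#' @return A one-row tibble: `shared_nodes`, `one_minus_nvi`, `null_mean`,
#'   `null_sd`, `null_max`, `p_value`, `n_permutations`.
#' @export
vi_permutation_null <- function(a, b, n_permutations = 1000, seed = 1) {
  va <- partition_vector(a); vb <- partition_vector(b)
  shared <- intersect(names(va), names(vb))
  if (length(shared) < 2) abort("need at least 2 shared nodes to compare partitions")
  xa <- va[shared]; xb <- vb[shared]
  obs <- 1 - min(max(vi_from_vectors(xa, xb) / log(length(shared)), 0), 1)
  null <- with_seed(seed, {
    vapply(seq_len(n_permutations), function(i) {
      1 - min(max(vi_from_vectors(sample(xa), sample(xb)) /
                    log(length(shared)), 0), 1)
    }, numeric(1))
  })
  tibble(shared_nodes = length(shared), one_minus_nvi = obs,
         null_mean = mean(null), null_sd = sd(null), null_max = max(null),
         p_value = (1 + sum(null >= obs)) / (n_permutations + 1),
         n_permutations = n_permutations)
}

#' Jaccard index of two node sets
#'
#' `|a intersect b| / |a union b|`.
#'
#' @param a,b Character vectors (node ids); at least one must be non-empty.
#' @return A number in \[0, 1\].
#' @export
jaccard <- function(a, b) {
  a <- unique(a); b <- unique(b)
  u <- length(union(a, b))
  if (u == 0) abort("Jaccard undefined for two empty sets")
  length(intersect(a, b)) / u
}

# Fixed, ordered colour vocabulary for community-type labels.
COMMUNITY_TYPE_COLOURS <- c(
  "green", "blue", "red", "orange", "purple", "yellow", "pink", "brown",
  "cyan", "magenta", "teal", "olive", "maroon", "navy", "lime", "coral",
  "gold", "silver", "indigo", "violet", "turquoise", "salmon", "khaki",
  "plum", "crimson", "amber", "emerald", "slate", "ivory", "charcoal")

#' Map communities across datasets into community-types
#'
#' Scores every cross-dataset community pair by the Jaccard index of their
#' OTU sets and records matches strictly above `threshold`. A
#' community-type is emitted wherever matched communities link up across
#' all datasets, one community per dataset; types are labelled from a fixed
#' ordered colour list in order of descending mean Jaccard. Communities
#' matched to more than one community in the same other dataset are
#' reported in the diagnostic and excluded from type formation.
#'
#' @param partitions A named list (dataset label -> `coocc_partition`) of
#'   at least 2 partitions.
#' @param threshold Jaccard match threshold, strict `>` (default 0.25).
#' @return A list of tibbles: `matches` (`dataset_a`, `community_a`,
#'   `dataset_b`, `community_b`, `jaccard`), `types` (`label`, `dataset`,
#'   `community_id`, `mean_jaccard`), and `multiple_matches` diagnostics.
#' @export
map_communities <- function(partitions, threshold = 0.25) {
  if (length(partitions) < 2 || is.null(names(partitions))) {
    abort("need a named list of at least 2 partitions")
  }
  ds <- names(partitions)
  sets <- imap(partitions, function(p, d) {
    split(p$otu_id, p$community_id)
  })
  pairs <- combn(ds, 2)
  matches <- list_rbind(map(seq_len(ncol(pairs)), function(j) {
    d1 <- pairs[1, j]; d2 <- pairs[2, j]
    grid <- expand.grid(community_a = names(sets[[d1]]),
                        community_b = names(sets[[d2]]),
                        stringsAsFactors = FALSE)
    jc <- map2_dbl(grid$community_a, grid$community_b,
                   ~ jaccard(sets[[d1]][[.x]], sets[[d2]][[.y]]))
    tibble(dataset_a = d1, community_a = as.integer(grid$community_a),
           dataset_b = d2, community_b = as.integer(grid$community_b),
           jaccard = jc)[jc > threshold, ]
  }))
  # diagnostic: a community matching > 1 community in one other dataset
  long <- bind_rows(
    transmute(matches, dataset = .data$dataset_a, community = .data$community_a,
              other_dataset = .data$dataset_b, other_community = .data$community_b),
    transmute(matches, dataset = .data$dataset_b, community = .data$community_b,
              other_dataset = .data$dataset_a, other_community = .data$community_a))
  multi <- long |>
    count(.data$dataset, .data$community, .data$other_dataset, name = "n_matches") |>
    filter(.data$n_matches > 1)
  if (nrow(multi) > 0) {
    warn(paste0(nrow(multi), " community/dataset pair(s) with multiple ",
                "matches; excluded from community-type formation"))
  }
  bad <- unique(paste(multi$dataset, multi$community))
  ok <- matches |>
    filter(!paste(.data$dataset_a, .data$community_a) %in% bad,
           !paste(.data$dataset_b, .data$community_b) %in% bad)
  # connected components of the match graph over (dataset, community) nodes
  types <- tibble(label = character(), dataset = character(),
                  community_id = integer(), mean_jaccard = numeric())
  if (nrow(ok) > 0) {
    vattr <- unique(tibble(
      name = c(paste(ok$dataset_a, ok$community_a, sep = "||"),
               paste(ok$dataset_b, ok$community_b, sep = "||"))))
    g <- igraph::graph_from_data_frame(
      data.frame(from = paste(ok$dataset_a, ok$community_a, sep = "||"),
                 to = paste(ok$dataset_b, ok$community_b, sep = "||"),
                 weight = ok$jaccard),
      directed = FALSE, vertices = vattr)
    comp <- igraph::components(g)
    cand <- map(seq_len(comp$no), function(ci) {
      members <- names(comp$membership)[comp$membership == ci]
      parts <- strsplit(members, "||", fixed = TRUE)
      d <- map_chr(parts, 1); cid <- as.integer(map_chr(parts, 2))
      if (!setequal(d, ds) || length(d) != length(ds)) return(NULL)
      sub <- igraph::induced_subgraph(g, members)
      tibble(dataset = d, community_id = cid,
             mean_jaccard = mean(igraph::E(sub)$weight))
    })
    cand <- cand[!map_lgl(cand, is.null)]
    if (length(cand) > 0) {
      ord <- order(-map_dbl(cand, ~ .x$mean_jaccard[1]))
      types <- list_rbind(imap(cand[ord], function(x, i) {
        lbl <- if (i <= length(COMMUNITY_TYPE_COLOURS)) {
          COMMUNITY_TYPE_COLOURS[i]
        } else {
          paste0("type", i)
        }
        mutate(x, label = lbl, .before = 1)
      }))
    }
  }
  list(matches = matches, types = types, multiple_matches = multi)
}
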