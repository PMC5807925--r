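# CoNet-style ensemble co-occurrence detection.
#
# Four measures (Pearson, Spearman, Bray-Curtis, symmetrised Kullback-
# Leibler) score every OTU pair; candidate edges are the pairs top-ranked by
# all four measures simultaneously, expanded in lock-step until target
# counts of co-presence ("positive") and exclusion ("negative") edges are
# reached. Each candidate then gets a ReBoot p-value per measure: the pair's
# abundances are permuted across samples, every sample's composition is
# renormalised, and the measure recomputed, so the null retains the spurious
# association induced by compositionality. A bootstrap over samples screens
# out unstable edges, per-measure p-values are merged by their minimum, and
# Benjamini-Hochberg FDR is applied across the surviving edges.

CONET_MEASURES <- c("pearson", "spearman", "bray_curtis", "kl")

# +1: high score means co-presence (correlations); -1: low score does
# (dissimilarities).
measure_polarity <- function(measure) {
  if (measure %in% c("pearson", "spearman")) 1 else -1
}

#' CoNet ensemble configuration
#'
#' @param target_pos_edges,target_neg_edges Candidate co-presence and
#'   exclusion edge counts the initial thresholds are expanded to reach
#'   (defaults 2000 each).
#' @param n_permutations ReBoot permutations per edge (default 1000).
#' @param n_bootstraps Sample bootstraps for the stability screen
#'   (default 1000).
#' @param kl_pseudocount Pseudocount added to the normalised vectors before
#'   the KL logs; `NULL` (default) means `1 / (2 * n_samples)`.
#' @param seed Integer seed.
#' @return A `conet_config` list.
#' @export
conet_config <- function(target_pos_edges = 2000, target_neg_edges = 2000,
                         n_permutations = 1000, n_bootstraps = 1000,
                         kl_pseudocount = NULL, seed = 1) {
  stopifnot(target_pos_edges >= 1, target_neg_edges >= 1, n_permutations >= 1)
  structure(list(target_pos_edges = target_pos_edges,
                 target_neg_edges = target_neg_edges,
                 n_permutations = n_permutations,
                 n_bootstraps = n_bootstraps,
                 kl_pseudocount = kl_pseudocount, seed = seed),
            class = "conet_config")
}

# Column-wise measure between two n x B matrices of pair abundances
# (columns = replicates). The workhorse for ReBoot and the bootstrap.
colwise_measure <- function(A, B, measure, kl_pseudocount) {
  switch(measure,
    pearson = {
      n <- nrow(A)
      ma <- colMeans(A); mb <- colMeans(B)
      sa <- sqrt(colMeans(A^2) - ma^2); sb <- sqrt(colMeans(B^2) - mb^2)
      num <- colMeans(A * B) - ma * mb
      out <- num / (sa * sb)
      out[sa == 0 | sb == 0] <- NA_real_
      out
    },
    spearman = {
      colwise_measure(apply(A, 2, rank), apply(B, 2, rank), "pearson", NULL)
    },
    bray_curtis = colSums(abs(A - B)) / colSums(A + B),
    kl = {
      P <- sweep(A, 2, colSums(A), "/") + kl_pseudocount
      Q <- sweep(B, 2, colSums(B), "/") + kl_pseudocount
      P <- sweep(P, 2, colSums(P), "/")
      Q <- sweep(Q, 2, colSums(Q), "/")
      0.5 * colSums(P * log(P / Q) + Q * log(Q / P))
    },
    abort(paste0("unknown measure: ", measure)))
}

#' Pairwise co-occurrence scores for one measure
#'
#' Scores every unordered OTU pair: Pearson/Spearman correlate abundance
#' vectors; Bray-Curtis is `sum|u - v| / sum(u + v)` across samples; KL is
#' the symmetrised Kullback-Leibler divergence between the two OTUs'
#' sample-normalised distributions (each vector rescaled to sum 1, a
#' pseudocount added, renormalised).
#'
#' @param r A relative-abundance tibble.
#' @param measure One of `"pearson"`, `"spearman"`, `"bray_curtis"`, `"kl"`.
#' @param kl_pseudocount Pseudocount for KL; default `1 / (2 * n_samples)`.
#' @return A `measure_scores` list: `measure`, symmetric `score` matrix,
#'   `polarity` (+1 high score = co-presence, -1 low score = co-presence).
#' @export
measure_scores <- function(r, measure = CONET_MEASURES, kl_pseudocount = NULL) {
  measure <- match.arg(measure)
  m <- count_matrix(r)
  m <- m[, sort(colnames(m)), drop = FALSE]
  if (any(colSums(m) == 0)) {
    abort(paste0("all-zero OTU vector(s): ",
                 paste(colnames(m)[colSums(m) == 0], collapse = ", ")))
  }
  D <- ncol(m)
  kl_pseudocount <- kl_pseudocount %||% (1 / (2 * nrow(m)))
  S <- switch(measure,
    pearson = suppressWarnings(cor(m)),
    spearman = suppressWarnings(cor(m, method = "spearman")),
    {
      S <- matrix(0, D, D, dimnames = list(colnames(m), colnames(m)))
      idx <- combn(D, 2)
      vals <- colwise_measure(m[, idx[1, ], drop = FALSE],
                              m[, idx[2, ], drop = FALSE],
                              measure, kl_pseudocount)
      S[t(idx)] <- vals
      S[t(idx[2:1, , drop = FALSE])] <- vals
      S
    })
  structure(list(measure = measure, score = S,
                 polarity = measure_polarity(measure)),
            class = "measure_scores")
}

#' Lock-step initial threshold selection across the four measures
#'
#' Each measure ranks all pairs toward co-presence and toward exclusion
#' (dissimilarity polarity inverted). Per-measure rank cutoffs grow in
#' lock-step, one rank at a time in every measure, and a pair becomes a
#' candidate when it is inside the cutoff of all four measures; expansion
#' stops when the co-presence and exclusion candidate sets reach their
#' targets (or all pairs are exhausted, with a warning).
#'
#' @param scores A named list of the four [measure_scores()] objects.
#' @param cfg A [conet_config()].
#' @return A list: `candidates` tibble (`otu_a`, `otu_b`, `polarity` in
#'   {"positive","negative"}) and `thresholds` tibble (per measure and
#'   polarity, the score at the final rank cutoff).
#' @export
select_initial_thresholds <- function(scores, cfg = conet_config()) {
  stopifnot(setequal(names(scores), CONET_MEASURES))
  ids <- colnames(scores[[1]]$score)
  idx <- combn(length(ids), 2)
  P <- ncol(idx)
  vals <- map(scores, ~ .x$score[t(idx)])
  one_side <- function(toward_pos, target) {
    ords <- map(CONET_MEASURES, function(ms) {
      v <- vals[[ms]] * scores[[ms]]$polarity  # high = co-presence for all
      if (toward_pos) order(-v) else order(v)
    })
    tally <- integer(P)
    chosen <- integer(0)
    cutoff <- 0L
    while (length(chosen) < target && cutoff < P) {
      cutoff <- cutoff + 1L
      for (o in ords) {
        p <- o[cutoff]
        tally[p] <- tally[p] + 1L
        if (tally[p] == 4L) chosen <- c(chosen, p)
      }
    }
    if (length(chosen) < target) {
      warn(paste0("pair universe exhausted with ", length(chosen),
                  " concordant ", if (toward_pos) "positive" else "negative",
                  " candidates (target ", target, ")"))
    }
    list(pairs = chosen, cutoff = cutoff,
         thresholds = map_dbl(CONET_MEASURES, function(ms) {
           o <- if (toward_pos) order(-vals[[ms]] * scores[[ms]]$polarity)
                else order(vals[[ms]] * scores[[ms]]$polarity)
           vals[[ms]][o[cutoff]]
         }))
  }
  pos <- one_side(TRUE, cfg$target_pos_edges)
  neg <- one_side(FALSE, cfg$target_neg_edges)
  both <- intersect(pos$pairs, neg$pairs)
  if (length(both) > 0) {
    warn(paste0(length(both), " pair(s) ranked as both co-presence and ",
                "exclusion candidates; dropped from both sets"))
    pos$pairs <- setdiff(pos$pairs, both)
    neg$pairs <- setdiff(neg$pairs, both)
  }
  cand <- bind_rows(
    tibble(otu_a = ids[idx[1, pos$pairs]], otu_b = ids[idx[2, pos$pairs]],
           polarity = "positive"),
    tibble(otu_a = ids[idx[1, neg$pairs]], otu_b = ids[idx[2, neg$pairs]],
           polarity = "negative"))
  thresholds <- tibble(
    measure = rep(CONET_MEASURES, 2),
    polarity = rep(c("positive", "negative"), each = 4),
    cutoff_rank = rep(c(pos$cutoff, neg$cutoff), each = 4),
    score_at_cutoff = c(pos$thresholds, neg$thresholds))
  list(candidates = cand, thresholds = thresholds)
}

# ReBoot null engine shared by reboot_pvalue() and conet_edges(): given the
# pair's fraction vectors and the rest-of-sample mass, builds the permuted
# and renormalised null replicates and returns the null score vector.
reboot_null_scores <- function(a, b, rest, measure, n_permutations, seed,
                               kl_pseudocount) {
  n <- length(a)
  with_seed(seed, {
    A <- replicate(n_permutations, sample(a))
    B <- replicate(n_permutations, sample(b))
    S <- rest + A + B  # renormalisation: every sample's composition sums to 1
    colwise_measure(A / S, B / S, measure, kl_pseudocount)
  })
}

#' ReBoot permutation-renormalisation p-value for one pair
#'
#' Permutes the two OTUs' abundances independently across samples,
#' renormalises every sample's composition, and recomputes the measure. The
#' two-sided p-value counts null scores at least as far from the null mean
#' as the observed score, with add-one smoothing. Direction is the sign of
#' (observed - null mean) mapped through the measure's polarity, so
#' "co-presence" is +1 for every measure.
#'
#' @param r A relative-abundance tibble.
#' @param pair Character vector of two OTU ids.
#' @param measure One of the four CoNet measures.
#' @param n_permutations Number of permutations (default 1000).
#' @param seed Integer seed.
#' @param kl_pseudocount KL pseudocount; default `1 / (2 * n_samples)`.
#' @return A list: `p`, `direction` (+1/-1, 0 if degenerate), `observed`,
#'   `null_mean`.
#' @export
reboot_pvalue <- function(r, pair, measure, n_permutations = 1000, seed = 1,
                          kl_pseudocount = NULL) {
  m <- count_matrix(r)
  if (!all(pair %in% colnames(m))) abort("pair not found in abundance table")
  kl_pseudocount <- kl_pseudocount %||% (1 / (2 * nrow(m)))
  a <- m[, pair[1]]; b <- m[, pair[2]]
  rest <- rowSums(m) - a - b
  obs <- colwise_measure(cbind(a), cbind(b), measure, kl_pseudocount)
  null <- reboot_null_scores(a, b, rest, measure, n_permutations, seed,
                             kl_pseudocount)
  null <- null[is.finite(null)]
  if (length(null) == 0 || sd(null) == 0 || !is.finite(obs)) {
    return(list(p = 1, direction = 0L, observed = obs,
                null_mean = if (length(null)) mean(null) else NA_real_))
  }
  mu <- mean(null)
  k <- sum(abs(null - mu) >= abs(obs - mu) - 1e-12)
  list(p = (1 + k) / (length(null) + 1),
       direction = as.integer(sign(obs - mu) * measure_polarity(measure)),
       observed = unname(obs), null_mean = mu)
}

#' CoNet-style ensemble edge table
#'
#' Runs the full ensemble: per-measure scores, lock-step candidate
#' selection, ReBoot p-values for every candidate under all four measures
#' (one shared permutation stream per pair), a bootstrap stability screen
#' (the edge is dropped when the ReBoot null mean falls inside the central
#' 95% interval of the measure's bootstrap distribution for any measure),
#' consensus direction (dropped on disagreement), per-edge merged
#' p = min over measures, and BH FDR across retained edges.
#'
#' @param r A relative-abundance tibble.
#' @param cfg A [conet_config()].
#' @return An edge-table tibble, method `"conet"`; `p_raw` is the merged
#'   minimum p, `p_adjusted` the BH q-value. Only retained edges appear.
#' @export
conet_edges <- function(r, cfg = conet_config()) {
  m <- count_matrix(r)
  m <- m[, sort(colnames(m)), drop = FALSE]
  n <- nrow(m)
  klp <- cfg$kl_pseudocount %||% (1 / (2 * n))
  scores <- setNames(
    map(CONET_MEASURES, ~ measure_scores(r, .x, kl_pseudocount = klp)),
    CONET_MEASURES)
  sel <- select_initial_thresholds(scores, cfg)
  cand <- sel$candidates
  if (nrow(cand) == 0) {
    return(edge_table(character(), character(), character(), numeric(),
                      integer(), numeric(), numeric()))
  }
  tot <- rowSums(m)
  seeds <- derive_seeds(cfg$seed, nrow(cand) + 1L)
  boot_idx <- with_seed(seeds[length(seeds)],
                        matrix(sample.int(n, n * cfg$n_bootstraps, replace = TRUE),
                               nrow = n))
  rows <- map(seq_len(nrow(cand)), function(i) {
    a <- m[, cand$otu_a[i]]; b <- m[, cand$otu_b[i]]
    rest <- tot - a - b
    # one permutation stream per pair, shared by the four measures
    perm <- with_seed(seeds[i], {
      A <- replicate(cfg$n_permutations, sample(a))
      B <- replicate(cfg$n_permutations, sample(b))
      S <- rest + A + B
      list(A = A / S, B = B / S)
    })
    Ab <- matrix(a[boot_idx], nrow = n)
    Bb <- matrix(b[boot_idx], nrow = n)
    res <- map(CONET_MEASURES, function(ms) {
      obs <- colwise_measure(cbind(a), cbind(b), ms, klp)
      null <- colwise_measure(perm$A, perm$B, ms, klp)
      null <- null[is.finite(null)]
      if (length(null) == 0 || sd(null) == 0 || !is.finite(obs)) {
        return(list(p = 1, dir = 0L, obs = obs, mu = NA_real_, stable = FALSE))
      }
      mu <- mean(null)
      k <- sum(abs(null - mu) >= abs(obs - mu) - 1e-12)
      boot <- colwise_measure(Ab, Bb, ms, klp)
      boot <- boot[is.finite(boot)]
      ci <- quantile(boot, c(0.025, 0.975), names = FALSE)
      list(p = (1 + k) / (length(null) + 1),
           dir = as.integer(sign(obs - mu) * measure_polarity(ms)),
           obs = unname(obs), mu = mu,
           stable = !(mu >= ci[1] && mu <= ci[2]))
    })
    dirs <- map_int(res, "dir")
    tibble(otu_a = cand$otu_a[i], otu_b = cand$otu_b[i],
           statistic = res[[1]]$obs,  # observed Pearson score
           direction = if (length(unique(dirs)) == 1L) dirs[1] else 0L,
           p_merged = min(map_dbl(res, "p")),
           stable = all(map_lgl(res, "stable")))
  })
  out <- list_rbind(rows)
  out <- filter(out, .data$stable, .data$direction != 0L)
  if (nrow(out) == 0) {
    return(edge_table(character(), character(), character(), numeric(),
                      integer(), numeric(), numeric()))
  }
  e <- edge_table(out$otu_a, out$otu_b, "conet", out$statistic,
                  out$direction, out$p_merged, bh_fdr(out$p_merged))
  arrange(e, .data$otu_a, .data$otu_b)
}
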