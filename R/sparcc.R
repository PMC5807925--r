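# SparCC-style basis correlations for compositional counts.
#
# Observed fractions are compositions, so ordinary correlations between them
# are biased. Following the log-ratio approach, the variance of
# log(f_i / f_j) over samples, t_ij, relates to unobserved "basis" variances
# w_i^2 and correlations rho_ij by t_ij = w_i^2 + w_j^2 - 2 rho_ij w_i w_j.
# Under a sparsity assumption (most rho close to 0) the row sums of t give a
# linear system for the w_i^2, after which rho follows. Strongly correlated
# pairs violate the sparsity assumption, so the strongest pairs are
# iteratively excluded from the row sums and the system re-solved.

#' SparCC configuration
#'
#' @param n_fraction_draws Posterior fraction draws averaged (median) per
#'   estimate (default 20).
#' @param exclusion_threshold Minimum |rho| for a pair to be excluded from
#'   the basis-variance system (default 0.1). Values >= 1 disable exclusion.
#' @param exclusion_iterations Maximum pairs excluded, one per iteration
#'   (default 10).
#' @param n_bootstraps Null tables for pseudo p-values (default 100).
#' @param seed Integer seed.
#' @return A `sparcc_config` list.
#' @export
sparcc_config <- function(n_fraction_draws = 20, exclusion_threshold = 0.1,
                          exclusion_iterations = 10, n_bootstraps = 100,
                          seed = 1) {
  stopifnot(n_fraction_draws >= 1, exclusion_threshold > 0, n_bootstraps >= 1)
  structure(list(n_fraction_draws = n_fraction_draws,
                 exclusion_threshold = exclusion_threshold,
                 exclusion_iterations = exclusion_iterations,
                 n_bootstraps = n_bootstraps, seed = seed),
            class = "sparcc_config")
}

#' Posterior fraction draw from counts
#'
#' One Dirichlet draw per sample with concentration `counts + 1`, giving
#' strictly positive fractions even where counts are zero. With
#' `mode = "ml"` the deterministic posterior mean `(count + 1) / (total + D)`
#' is returned instead (useful for reproducible unit tests).
#'
#' @param t A count-table tibble.
#' @param seed Integer seed.
#' @param mode `"draw"` (default) or `"ml"`.
#' @return A relative-abundance tibble with strictly positive rows summing to 1.
#' @export
estimate_fractions <- function(t, seed = 1, mode = c("draw", "ml")) {
  mode <- match.arg(mode)
  m <- count_matrix(t)
  if (mode == "ml") {
    f <- (m + 1) / (rowSums(m) + ncol(m))
  } else {
    f <- with_seed(seed, {
      g <- matrix(rgamma(length(m), shape = as.vector(m) + 1, rate = 1),
                  nrow = nrow(m))
      g / rowSums(g)
    })
    dimnames(f) <- dimnames(m)
  }
  matrix_to_table(f)
}

# Log-ratio variance matrix t_ij = Var_s log(f_i / f_j), computed from the
# covariance of log fractions: t_ij = V_ii + V_jj - 2 C_ij.
log_ratio_variance <- function(fm) {
  C <- stats::cov(log(fm))
  d <- diag(C)
  tij <- outer(d, d, `+`) - 2 * C
  diag(tij) <- 0
  # numerical guard: variances are non-negative by construction
  tij[tij < 0] <- 0
  tij
}

# Solve the sparsity-approximation system given an inclusion mask over pairs
# (logical DxD, symmetric, FALSE diagonal/excluded). Returns basis variances.
solve_basis_variances <- function(tij, include) {
  mi <- rowSums(include)
  M <- include * 1
  diag(M) <- mi
  if (any(mi == 0)) abort("an OTU has no included pairs left in the basis system")
  w2 <- as.vector(solve(M, rowSums(tij * include)))
  if (any(w2 <= 0)) {
    warn(paste0("flooring ", sum(w2 <= 0),
                " non-positive basis variance(s) at 1e-12"))
    w2[w2 <= 0] <- 1e-12
  }
  names(w2) <- rownames(tij)
  w2
}

rho_from_basis <- function(tij, w2) {
  w <- sqrt(w2)
  rho <- (outer(w2, w2, `+`) - tij) / (2 * outer(w, w))
  rho <- pmin(pmax(rho, -1), 1)
  diag(rho) <- 1
  rho
}

# One basis estimate with iterative strongest-pair exclusion.
basis_with_exclusion <- function(tij, threshold, iterations) {
  D <- nrow(tij)
  include <- matrix(TRUE, D, D)
  diag(include) <- FALSE
  w2 <- solve_basis_variances(tij, include)
  rho <- rho_from_basis(tij, w2)
  if (threshold < 1) {
    for (it in seq_len(iterations)) {
      cand <- abs(rho)
      cand[!include] <- -Inf
      cand[lower.tri(cand, diag = TRUE)] <- -Inf
      top <- which.max(cand)
      if (cand[top] < threshold) break
      i <- row(cand)[top]; j <- col(cand)[top]
      include[i, j] <- include[j, i] <- FALSE
      w2 <- solve_basis_variances(tij, include)
      rho <- rho_from_basis(tij, w2)
    }
  }
  list(rho = rho, omega_sq = w2, tij = tij)
}

#' Basis correlations from one fraction table
#'
#' Computes the log-ratio variance matrix and solves the sparsity
#' approximation for basis variances and correlations, without iterative
#' exclusion (see [sparcc()] for the full estimator).
#'
#' @param f A strictly positive relative-abundance tibble with >= 4 OTUs.
#' @return A `sparcc_result` list with `rho`, `omega_sq`, `tij`.
#' @export
basis_correlations <- function(f) {
  fm <- count_matrix(f)
  if (ncol(fm) < 4) abort("SparCC needs at least 4 OTUs")
  if (any(fm <= 0)) abort("fractions must be strictly positive")
  tij <- log_ratio_variance(fm)
  include <- matrix(TRUE, ncol(fm), ncol(fm)); diag(include) <- FALSE
  w2 <- solve_basis_variances(tij, include)
  structure(list(rho = rho_from_basis(tij, w2), omega_sq = w2, tij = tij,
                 p = NULL, otu_ids = colnames(fm)),
            class = "sparcc_result")
}

# Vectorised row-wise median of a (rows x draws) matrix.
row_medians <- function(X) {
  n <- ncol(X)
  Xs <- matrix(X[order(row(X), X)], nrow = nrow(X), byrow = TRUE)
  if (n %% 2 == 1) Xs[, (n + 1) / 2] else (Xs[, n / 2] + Xs[, n / 2 + 1]) / 2
}

# Matrix-level fraction draw (Dirichlet with +1 prior), no tibble overhead.
fraction_draw <- function(m, seed) {
  with_seed(seed, {
    g <- matrix(rgamma(length(m), shape = as.vector(m) + 1, rate = 1),
                nrow = nrow(m))
    g / rowSums(g)
  })
}

# Matrix-level SparCC core shared by sparcc() and the bootstrap null loop.
sparcc_matrix <- function(m, cfg) {
  D <- ncol(m)
  seeds <- derive_seeds(cfg$seed, cfg$n_fraction_draws)
  nd <- cfg$n_fraction_draws
  rho_s <- matrix(NA_real_, D * D, nd)
  tij_s <- matrix(NA_real_, D * D, nd)
  w2_s <- matrix(NA_real_, D, nd)
  for (k in seq_len(nd)) {
    fm <- fraction_draw(m, seeds[k])
    est <- basis_with_exclusion(log_ratio_variance(fm),
                                cfg$exclusion_threshold,
                                cfg$exclusion_iterations)
    rho_s[, k] <- est$rho
    tij_s[, k] <- est$tij
    w2_s[, k] <- est$omega_sq
  }
  list(rho = matrix(row_medians(rho_s), D, D),
       tij = matrix(row_medians(tij_s), D, D),
       omega_sq = row_medians(w2_s))
}

#' SparCC basis correlation estimate
#'
#' For each of `n_fraction_draws` posterior fraction draws, computes the
#' log-ratio variance matrix and solves the basis system with iterative
#' exclusion of the strongest pairs; the reported matrices are elementwise
#' medians across draws.
#'
#' @param t A count-table tibble with >= 4 OTUs.
#' @param cfg A [sparcc_config()].
#' @return A `sparcc_result` list with `rho`, `omega_sq`, `tij`, `otu_ids`
#'   (and `p = NULL`; see [sparcc_pseudo_pvalues()]).
#' @export
sparcc <- function(t, cfg = sparcc_config()) {
  m <- count_matrix(t)
  if (ncol(m) < 4) abort("SparCC needs at least 4 OTUs")
  est <- sparcc_matrix(m, cfg)
  rho <- est$rho; tij <- est$tij
  dimnames(rho) <- dimnames(tij) <- list(colnames(m), colnames(m))
  structure(list(rho = rho, omega_sq = setNames(est$omega_sq, colnames(m)),
                 tij = tij, p = NULL, otu_ids = colnames(m)),
            class = "sparcc_result")
}

#' Bootstrap pseudo p-values for SparCC correlations
#'
#' Null tables are formed by independently permuting each OTU's counts
#' across samples, destroying pairwise association while keeping marginal
#' count distributions; SparCC is run on each and the two-tailed pseudo
#' p-value for a pair is `(1 + #{|rho_null| >= |rho_obs|}) / (B + 1)`. The
#' add-one estimator keeps p away from exactly zero.
#'
#' @param t The count table `observed` was estimated from.
#' @param observed The `sparcc_result` for `t` under the same `cfg`.
#' @param cfg A [sparcc_config()]; `n_bootstraps` null tables are used.
#' @return The `sparcc_result` with a symmetric `p` matrix filled in.
#' @export
sparcc_pseudo_pvalues <- function(t, observed, cfg = sparcc_config()) {
  m <- count_matrix(t)
  B <- cfg$n_bootstraps
  seeds <- derive_seeds(cfg$seed + 1L, B)
  exceed <- matrix(0, ncol(m), ncol(m))
  target <- abs(observed$rho)
  for (b in seq_len(B)) {
    perm <- with_seed(seeds[b], apply(m, 2, sample))
    null_cfg <- cfg
    null_cfg$seed <- seeds[b]
    rho_null <- sparcc_matrix(perm, null_cfg)$rho
    exceed <- exceed + (abs(rho_null) >= target)
  }
  p <- (1 + exceed) / (B + 1)
  diag(p) <- 1
  out <- observed
  out$p <- p
  out
}

#' Edge table from a SparCC result
#'
#' @param res A `sparcc_result` with p-values filled in.
#' @return An edge-table tibble, method `"sparcc"`, p = pseudo p.
#' @export
sparcc_edges <- function(res) {
  if (is.null(res$p)) abort("run sparcc_pseudo_pvalues() first")
  ids <- sort(res$otu_ids)
  rho <- res$rho[ids, ids]
  p <- res$p[ids, ids]
  idx <- combn(length(ids), 2)
  a <- idx[1, ]; b <- idx[2, ]
  r <- rho[cbind(a, b)]
  edge_table(ids[a], ids[b], method = "sparcc", statistic = r,
             direction = ifelse(r >= 0, 1L, -1L),
             p_raw = p[cbind(a, b)], p_adjusted = p[cbind(a, b)])
}

#' @export
print.sparcc_result <- function(x, ...) {
  cat("SparCC result over", length(x$otu_ids), "OTUs;",
      if (is.null(x$p)) "no p-values yet" else "pseudo p-values attached", "\n")
  invisible(x)
}

#' @export
tidy.sparcc_result <- function(x, ...) {
  ids <- sort(x$otu_ids)
  idx <- combn(length(ids), 2)
  a <- idx[1, ]; b <- idx[2, ]
  rho <- x$rho[ids, ids]
  out <- tibble(otu_a = ids[a], otu_b = ids[b], rho = rho[cbind(a, b)])
  if (!is.null(x$p)) out$p <- x$p[ids, ids][cbind(a, b)]
  out
}
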