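# Pairwise co-occurrence edge tables.
#
# All estimators emit the shared "edge table" tibble:
#   otu_a, otu_b, method, statistic, direction, p_raw, p_adjusted
# with otu_a < otu_b under the fixed id ordering, one row per unordered OTU
# pair (complete over C(D,2) pairs), direction in {+1, -1} (0 marks the
# zero-variance sentinel, never matched at intersection time), and p values
# in [0, 1]. Keeping the pair universe identical across methods is what
# makes the downstream directional intersection well defined.

edge_table <- function(otu_a, otu_b, method, statistic, direction, p_raw, p_adjusted) {
  tibble(otu_a = otu_a, otu_b = otu_b, method = method,
         statistic = statistic, direction = as.integer(direction),
         p_raw = pmin(pmax(p_raw, 0), 1), p_adjusted = pmin(pmax(p_adjusted, 0), 1))
}

validate_edge_table <- function(e) {
  need <- c("otu_a", "otu_b", "method", "statistic", "direction", "p_raw", "p_adjusted")
  if (!all(need %in% names(e))) abort("edge table is missing required columns")
  if (any(e$otu_a >= e$otu_b)) abort("edge table pairs must satisfy otu_a < otu_b")
  if (anyDuplicated(pair_key(e$otu_a, e$otu_b))) abort("duplicate pairs in edge table")
  invisible(e)
}

# Shared engine for the two rank/product-moment estimators.
cor_edges <- function(r, method) {
  m <- count_matrix(r)
  n <- nrow(m)
  if (n < 3) abort("need at least 3 samples for correlation p-values")
  if (ncol(m) < 2) abort("need at least 2 OTUs")
  m <- m[, sort(colnames(m)), drop = FALSE]
  D <- ncol(m)
  sds <- apply(m, 2, sd)
  C <- suppressWarnings(cor(m, method = method))
  idx <- combn(D, 2)
  a <- idx[1, ]; b <- idx[2, ]
  rho <- C[cbind(a, b)]
  degenerate <- sds[a] == 0 | sds[b] == 0
  # two-tailed p via the t transform with n - 2 df
  tt <- rho * sqrt((n - 2) / pmax(1 - rho^2, .Machine$double.eps))
  p <- 2 * pt(-abs(tt), df = n - 2)
  p[abs(rho) >= 1] <- 0
  p[degenerate] <- 1
  rho[degenerate] <- NA_real_
  dir <- ifelse(degenerate, 0L, ifelse(rho >= 0, 1L, -1L))
  edge_table(colnames(m)[a], colnames(m)[b],
             method = if (method == "pearson") "pearson" else "spearman",
             statistic = rho, direction = dir,
             p_raw = p, p_adjusted = bonferroni(p))
}

#' Pearson co-occurrence edges
#'
#' Pearson correlation between every unordered pair of OTU relative-abundance
#' vectors, with two-tailed p-values from the t transform on n - 2 degrees
#' of freedom, Bonferroni-adjusted over the number of pairs. Pairs involving
#' a zero-variance OTU are kept as sentinels (p = 1, direction = 0) so all
#' methods share one pair universe.
#'
#' @param r A relative-abundance tibble (see [relative_abundance()]).
#' @return An edge-table tibble with one row per OTU pair.
#' @export
pearson_edges <- function(r) cor_edges(r, "pearson")

#' Spearman co-occurrence edges
#'
#' Spearman rank correlation (mid-ranks for ties) with two-tailed p-values
#' from the t approximation, Bonferroni-adjusted over the number of pairs.
#'
#' @inheritParams pearson_edges
#' @return An edge-table tibble with one row per OTU pair.
#' @export
spearman_edges <- function(r) cor_edges(r, "spearman")

#' Bonferroni family-wise adjustment
#'
#' `min(1, p * m)` with `m = length(p)`; order-preserving.
#'
#' @param p Vector of p-values in \[0, 1\].
#' @return Adjusted p-values.
#' @export
bonferroni <- function(p) {
  stopifnot(all(p >= 0 & p <= 1))
  p.adjust(p, method = "bonferroni")
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted q-values, capped at 1.
#'
#' @param p Vector of p-values in \[0, 1\].
#' @return q-values.
#' @export
bh_fdr <- function(p) {
  stopifnot(all(p >= 0 & p <= 1))
  p.adjust(p, method = "BH")
}

#' Write an edge table as TSV
#'
#' @param e An edge-table tibble.
#' @param path Output path.
#' @export
write_edge_table <- function(e, path) {
  validate_edge_table(e)
  readr::write_tsv(e, path, progress = FALSE)
}
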