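# OTU count tables: reading, validation, filtering, normalisation, diversity.
#
# A count table is a wide tibble: a `sample_id` character column followed by
# one non-negative integer column per OTU. Sample ids and OTU column names
# must be unique. This shape pipes naturally through dplyr while the numeric
# work happens on the matrix view (`count_matrix()`).

#' Build and validate an OTU count table
#'
#' Constructs the canonical count-table tibble (samples in rows, OTUs in
#' columns, `sample_id` first) from a matrix or data frame and checks its
#' invariants: counts are non-negative integers, and sample/OTU identifiers
#' are unique.
#'
#' @param x A numeric matrix (samples x OTUs, rownames = sample ids) or a
#'   data frame with a `sample_id` column and one numeric column per OTU.
#' @return A validated count-table tibble.
#' @examples
#' m <- matrix(c(5L, 0L, 3L, 2L), 2, 2,
#'   dimnames = list(c("s1", "s2"), c("otu1", "otu2")))
#' as_count_table(m)
#' @export
as_count_table <- function(x) {
  if (is.matrix(x)) {
    if (is.null(rownames(x)) || is.null(colnames(x))) {
      abort("count matrix must have sample rownames and OTU colnames")
    }
    x <- tibble(sample_id = rownames(x), as_tibble(x))
  }
  x <- as_tibble(x)
  if (!"sample_id" %in% names(x)) {
    abort("count table must have a 'sample_id' column")
  }
  x <- relocate(x, "sample_id")
  validate_count_table(x)
  x
}

validate_count_table <- function(t) {
  if (!"sample_id" %in% names(t)) abort("count table must have a 'sample_id' column")
  if (anyDuplicated(t$sample_id)) abort("duplicate sample ids in count table")
  otus <- setdiff(names(t), "sample_id")
  if (anyDuplicated(otus)) abort("duplicate OTU ids in count table")
  m <- count_matrix(t)
  if (any(!is.finite(m))) abort("count table contains non-finite values")
  if (any(m < 0)) abort("count table contains negative counts")
  if (any(abs(m - round(m)) > 1e-8)) abort("count table contains non-integer counts")
  invisible(t)
}

#' Matrix view of a count or abundance table
#'
#' @param t A count-table or relative-abundance tibble.
#' @return A numeric matrix, samples x OTUs, with sample ids as rownames.
#' @export
count_matrix <- function(t) {
  otus <- setdiff(names(t), "sample_id")
  m <- as.matrix(t[, otus, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- t$sample_id
  m
}

matrix_to_table <- function(m) {
  tibble(sample_id = rownames(m), as_tibble(m))
}

#' Read an OTU count table from TSV or BIOM
#'
#' TSV tables may have samples in rows (first column = sample id, header =
#' OTU ids) or OTUs in rows; the orientation can be declared or, when a
#' vector of known sample ids is supplied, auto-detected from identifier
#' overlap. BIOM files (JSON dialect) are read through the biomformat
#' package, whose observation x sample matrix is transposed to the
#' samples x OTUs convention.
#'
#' @param path Path to the file.
#' @param format `"tsv"` or `"biom"`.
#' @param orientation For TSV: `"samples"` (rows are samples), `"otus"`
#'   (rows are OTUs), or `"auto"` (requires `sample_ids`).
#' @param sample_ids Optional known sample ids used by `orientation = "auto"`.
#' @return A validated count-table tibble.
#' @export
read_count_table <- function(path, format = c("tsv", "biom"),
                             orientation = c("samples", "otus", "auto"),
                             sample_ids = NULL) {
  format <- match.arg(format)
  orientation <- match.arg(orientation)
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  if (format == "biom") {
    if (!requireNamespace("biomformat", quietly = TRUE)) {
      abort("the biomformat package is required to read BIOM files")
    }
    b <- biomformat::read_biom(path)
    m <- t(as.matrix(biomformat::biom_data(b)))
    return(as_count_table(m))
  }
  d <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (ncol(d) < 2) abort(paste0("malformed count table (need id column + counts): ", path))
  first <- names(d)[1]
  row_ids <- as.character(d[[1]])
  if (orientation == "auto") {
    if (is.null(sample_ids)) abort("orientation = 'auto' needs sample_ids")
    in_rows <- mean(row_ids %in% sample_ids)
    in_cols <- mean(names(d)[-1] %in% sample_ids)
    orientation <- if (in_rows >= in_cols) "samples" else "otus"
  }
  m <- as.matrix(d[, -1, drop = FALSE])
  if (!is.numeric(m)) abort(paste0("non-numeric counts in ", path))
  rownames(m) <- row_ids
  if (orientation == "otus") m <- t(m)
  as_count_table(m)
}

#' Write a count table as TSV (samples in rows)
#'
#' @param t A count-table tibble.
#' @param path Output path.
#' @export
write_count_table <- function(t, path) {
  validate_count_table(t)
  readr::write_tsv(t, path, progress = FALSE)
}

#' Per-sample sequencing depth
#'
#' @param t A count-table tibble.
#' @return A tibble with `sample_id` and `depth` (total counts).
#' @export
sample_depths <- function(t) {
  m <- count_matrix(t)
  tibble(sample_id = rownames(m), depth = unname(rowSums(m)))
}

#' Remove shallow samples and near-absent OTUs
#'
#' Drops samples whose total count is below `min_sample_depth`, then drops
#' OTUs observed (count > 0) in fewer than `min_otu_samples` of the
#' remaining samples. The sample filter is applied first so OTU occupancy is
#' assessed on the retained samples only.
#'
#' @param t A count-table tibble.
#' @param min_sample_depth Minimum total counts per sample (default 10000).
#' @param min_otu_samples Minimum number of samples an OTU must occur in
#'   (default 2, i.e. OTUs seen in a single sample are removed).
#' @return The filtered count-table tibble.
#' @export
filter_low_quality <- function(t, min_sample_depth = 10000, min_otu_samples = 2) {
  validate_count_table(t)
  m <- count_matrix(t)
  keep_s <- rowSums(m) >= min_sample_depth
  if (!any(keep_s)) abort("all samples removed by depth filter")
  m <- m[keep_s, , drop = FALSE]
  keep_o <- colSums(m > 0) >= min_otu_samples
  as_count_table(m[, keep_o, drop = FALSE])
}

#' Keep OTUs present in at least a fraction of samples
#'
#' An OTU is retained when its occupancy (samples with a nonzero count)
#' divided by the number of samples is at least `min_fraction`; the boundary
#' is inclusive. Samples are unchanged. Prevalence is intended to be
#' computed on the raw (unrarefied) table.
#'
#' @param t A count-table tibble.
#' @param min_fraction Minimum occupancy fraction in (0, 1] (default 0.25).
#' @return The filtered count-table tibble.
#' @export
prevalence_filter <- function(t, min_fraction = 0.25) {
  stopifnot(min_fraction > 0, min_fraction <= 1)
  validate_count_table(t)
  m <- count_matrix(t)
  keep <- colSums(m > 0) / nrow(m) >= min_fraction
  as_count_table(m[, keep, drop = FALSE])
}

#' Rarefy every sample to a fixed depth
#'
#' Subsamples each sample's counts without replacement (multivariate
#' hypergeometric) to exactly `depth` reads, reproducibly for a given seed.
#'
#' @param t A count-table tibble; every sample must have total >= `depth`.
#' @param depth Target depth.
#' @param seed Integer seed.
#' @return A count-table tibble in which every sample sums to `depth`.
#' @export
rarefy <- function(t, depth, seed) {
  validate_count_table(t)
  m <- count_matrix(t)
  tot <- rowSums(m)
  if (any(tot < depth)) {
    abort(paste0("samples shallower than rarefaction depth ", depth, ": ",
                 paste(rownames(m)[tot < depth], collapse = ", ")))
  }
  # vegan emits a heuristic warning when the smallest nonzero count is > 1;
  # our preconditions already guarantee valid integer counts
  out <- with_seed(seed, suppressWarnings(vegan::rrarefy(m, depth)))
  as_count_table(out)
}

#' Relative abundance table
#'
#' Divides each sample's counts by its total. The result keeps the count
#' table's shape; each sample row sums to 1.
#'
#' @param t A count-table tibble with strictly positive sample totals.
#' @return A relative-abundance tibble.
#' @export
relative_abundance <- function(t) {
  validate_count_table(t)
  m <- count_matrix(t)
  tot <- rowSums(m)
  if (any(tot == 0)) {
    abort(paste0("zero-total samples: ",
                 paste(rownames(m)[tot == 0], collapse = ", ")))
  }
  matrix_to_table(m / tot)
}

#' Rarefaction-averaged alpha diversity
#'
#' For each sample, the chosen index is computed on `n_reps` independent
#' rarefactions to `depth` and averaged. Shannon uses natural logarithms
#' (configurable via `base`); inverse Simpson is 1 / sum(p_i^2).
#'
#' @param t A count-table tibble.
#' @param metric `"shannon"` or `"inv_simpson"`.
#' @param depth Rarefaction depth (default 10000).
#' @param n_reps Number of rarefactions averaged (default 10).
#' @param seed Integer seed.
#' @param base Logarithm base for Shannon (default `exp(1)`).
#' @return A tibble with `sample_id`, `metric`, `value`.
#' @export
alpha_diversity <- function(t, metric = c("shannon", "inv_simpson"),
                            depth = 10000, n_reps = 10, seed, base = exp(1)) {
  metric <- match.arg(metric)
  seeds <- derive_seeds(seed, n_reps)
  vals <- map(seeds, function(s) {
    m <- count_matrix(rarefy(t, depth, s))
    if (metric == "shannon") {
      vegan::diversity(m, index = "shannon", base = base)
    } else {
      vegan::diversity(m, index = "invsimpson")
    }
  })
  tibble(sample_id = t$sample_id,
         metric = metric,
         value = unname(Reduce(`+`, vals) / n_reps))
}

#' Fraction of zero cells in a count table
#'
#' @param t A non-empty count-table tibble.
#' @return A proportion in \[0, 1\].
#' @export
sparsity <- function(t) {
  m <- count_matrix(t)
  if (length(m) == 0) abort("empty count table")
  mean(m == 0)
}

#' Read per-sample metadata
#'
#' Expects a TSV with a `sample_id` column and any of `age`, `bmi`, `sex`,
#' `depth`. Sex is normalised to male/female/unknown.
#'
#' @param path Path to a TSV file.
#' @return A metadata tibble.
#' @export
read_sample_metadata <- function(path) {
  d <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (!"sample_id" %in% names(d)) abort("metadata must have a 'sample_id' column")
  if (anyDuplicated(d$sample_id)) abort("duplicate sample ids in metadata")
  if ("sex" %in% names(d)) {
    s <- tolower(as.character(d$sex))
    s[!s %in% c("male", "female")] <- "unknown"
    d$sex <- s
  }
  for (v in intersect(c("age", "bmi"), names(d))) {
    if (any(d[[v]] < 0, na.rm = TRUE)) abort(paste0("negative ", v, " in metadata"))
  }
  d
}

#' Read Greengenes-style taxonomy assignments
#'
#' Expects a TSV with columns `otu_id` and `lineage`, the lineage being a
#' semicolon-separated ranked string (`k__...; p__...; ...`).
#'
#' @param path Path to a TSV file.
#' @return A tibble with `otu_id` and `lineage`.
#' @export
read_taxonomy <- function(path) {
  d <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("otu_id", "lineage") %in% names(d))) {
    abort("taxonomy must have 'otu_id' and 'lineage' columns")
  }
  if (anyDuplicated(d$otu_id)) abort("duplicate OTU ids in taxonomy")
  d
}

#' Read representative sequences from FASTA
#'
#' @param path Path to an uncompressed FASTA file.
#' @return A tibble with `otu_id` and `sequence`.
#' @export
read_rep_seqs <- function(path) {
  lines <- readr::read_lines(path, progress = FALSE)
  hdr <- grepl("^>", lines)
  if (!any(hdr)) abort(paste0("no FASTA records in ", path))
  ids <- sub("^>\\s*(\\S+).*$", "\\1", lines[hdr])
  grp <- cumsum(hdr)
  seqs <- vapply(split(lines[!hdr], grp[!hdr]),
                 function(x) toupper(paste(x, collapse = "")), character(1))
  if (anyDuplicated(ids)) abort("duplicate OTU ids in FASTA")
  if (any(nchar(seqs) == 0)) abort("empty sequence in FASTA")
  if (any(grepl("[^ACGTN]", seqs))) abort("sequences must be over A/C/G/T/N")
  tibble(otu_id = ids, sequence = unname(seqs))
}
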