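# Community characterisation: per-sample community abundance, host
# association regressions, taxonomy tallies, within-community sequence
# identity, and the community size vs OTU abundance correlation.

#' Per-sample community relative abundance
#'
#' For each sample and community: the sum of the community's OTU counts
#' divided by the sample's total counts (over all OTUs in the table, so
#' OTUs outside the network contribute to the denominator and community
#' values sum to at most 1 per sample).
#'
#' @param t A count-table tibble whose OTUs include the partition's.
#' @param part A `coocc_partition`.
#' @return A tibble: `sample_id` plus one column `c<community_id>` per
#'   community, values in \[0, 1\].
#' @export
community_abundance <- function(t, part) {
  m <- count_matrix(t)
  tot <- rowSums(m)
  if (any(tot == 0)) {
    abort(paste0("zero-depth samples: ",
                 paste(rownames(m)[tot == 0], collapse = ", ")))
  }
  if (!all(part$otu_id %in% colnames(m))) {
    abort("partition contains OTUs absent from the count table")
  }
  groups <- split(part$otu_id, part$community_id)
  vals <- map(groups, function(otus) {
    rowSums(m[, otus, drop = FALSE]) / tot
  })
  out <- tibble(sample_id = rownames(m))
  for (cid in names(groups)) out[[paste0("c", cid)]] <- unname(vals[[cid]])
  out
}

#' Log-transform community abundances
#'
#' Elementwise `log10(value + pseudo)`; zero abundance maps to
#' `log10(pseudo)` (-6 at the default).
#'
#' @param a A community-abundance tibble from [community_abundance()].
#' @param pseudo Pseudo-abundance (default 1e-6).
#' @return The transformed tibble (same shape).
#' @export
log_abundance <- function(a, pseudo = 1e-6) {
  mutate(a, across(-"sample_id", ~ log10(.x + pseudo)))
}

#' Host-phenotype association regressions per community
#'
#' Per community: ordinary least squares of log abundance on
#' BMI + age + sex + sequencing depth (sex as a categorical covariate with
#' "unknown" as its own level). Coefficients and two-tailed p-values are
#' extracted for BMI and age and BH-FDR adjusted per phenotype across
#' communities. Samples with missing covariates are dropped listwise;
#' constant-abundance communities are flagged and excluded from the FDR
#' family.
#'
#' @param a A log-transformed community-abundance tibble.
#' @param m A metadata tibble with `sample_id`, `bmi`, `age`, `sex`, `depth`.
#' @return A tibble: `community_id`, `phenotype` ("bmi"/"age"), `beta`,
#'   `p`, `q`, `n_samples`; attribute `excluded` lists constant communities.
#' @export
associate <- function(a, m) {
  need <- c("sample_id", "bmi", "age", "sex", "depth")
  if (!all(need %in% names(m))) {
    abort(paste0("metadata must have columns: ", paste(need, collapse = ", ")))
  }
  d <- inner_join(a, m[, need], by = "sample_id")
  if (nrow(d) == 0) abort("no samples shared between abundances and metadata")
  d <- d[complete.cases(d[, c("bmi", "age", "sex", "depth")]), ]
  d$sex <- factor(d$sex)
  covars <- c("bmi", "age", if (nlevels(d$sex) > 1) "sex", "depth")
  fml <- stats::reformulate(covars, response = "y")
  comms <- setdiff(names(a), "sample_id")
  excluded <- character(0)
  rows <- list()
  for (cc in comms) {
    y <- d[[cc]]
    if (sd(y) == 0) {
      excluded <- c(excluded, cc)
      next
    }
    dd <- d
    dd$y <- y
    fit <- lm(fml, data = dd)
    sm <- summary(fit)$coefficients
    for (ph in c("bmi", "age")) {
      rows[[length(rows) + 1]] <- tibble(
        community_id = as.integer(sub("^c", "", cc)), phenotype = ph,
        beta = sm[ph, "Estimate"], p = sm[ph, "Pr(>|t|)"],
        n_samples = nrow(d))
    }
  }
  if (length(excluded) > 0) {
    warn(paste0("constant-abundance communities excluded from FDR family: ",
                paste(excluded, collapse = ", ")))
  }
  out <- list_rbind(rows)
  out <- out |>
    group_by(.data$phenotype) |>
    mutate(q = bh_fdr(.data$p)) |>
    ungroup() |>
    select("community_id", "phenotype", "beta", "p", "q", "n_samples")
  attr(out, "excluded") <- excluded
  out
}

# Greengenes rank prefixes, kingdom -> species.
GG_RANKS <- c(kingdom = "k", phylum = "p", class = "c", order = "o",
              family = "f", genus = "g", species = "s")

#' Per-community taxon counts at a rank
#'
#' Counts the OTUs in each community assigned to each taxon label at the
#' requested rank of the Greengenes-style lineage. OTUs unassigned at that
#' rank are bucketed under their assigned lineage prefix followed by
#' `";unassigned"`.
#'
#' @param part A `coocc_partition`.
#' @param tax A taxonomy tibble (`otu_id`, `lineage`).
#' @param level Rank name: one of kingdom, phylum, class, order, family,
#'   genus, species.
#' @return A tibble: `community_id`, `taxon`, `n_otus`.
#' @export
taxonomy_summary <- function(part, tax, level = "phylum") {
  level <- match.arg(level, names(GG_RANKS))
  rank_i <- match(level, names(GG_RANKS))
  if (!all(part$otu_id %in% tax$otu_id)) {
    abort("taxonomy does not cover all partition OTUs")
  }
  lin <- setNames(tax$lineage, tax$otu_id)[part$otu_id]
  label_at <- function(l) {
    toks <- trimws(strsplit(l, ";", fixed = TRUE)[[1]])
    assigned <- grepl("^[a-z]__.+", toks)
    if (length(toks) >= rank_i && assigned[rank_i]) return(toks[rank_i])
    keep <- toks[seq_len(min(length(toks), rank_i))]
    keep <- keep[cumprod(grepl("^[a-z]__.+", keep)) == 1]
    paste0(paste(keep, collapse = ";"), ";unassigned")
  }
  tibble(community_id = part$community_id,
         taxon = vapply(lin, label_at, character(1), USE.NAMES = FALSE)) |>
    count(.data$community_id, .data$taxon, name = "n_otus") |>
    arrange(.data$community_id, desc(.data$n_otus))
}

#' Alignment scoring scheme
#'
#' Defaults: match +1, mismatch -1, gap open -2, gap extend -1. A gap of
#' length L costs `gap_open + (L - 1) * gap_extend`.
#'
#' @param match,mismatch,gap_open,gap_extend Scores (penalties negative).
#' @return An `alignment_scoring` list.
#' @export
alignment_scoring <- function(match = 1, mismatch = -1, gap_open = -2,
                              gap_extend = -1) {
  stopifnot(match > 0, mismatch <= 0, gap_open <= 0, gap_extend <= 0,
            abs(gap_open) >= abs(gap_extend))
  structure(list(match = match, mismatch = mismatch, gap_open = gap_open,
                 gap_extend = gap_extend), class = "alignment_scoring")
}

# Identity of one globally aligned pair under the scoring scheme.
pair_identity <- function(s1, s2, scoring) {
  if (!requireNamespace("Biostrings", quietly = TRUE)) {
    abort("the Biostrings package is required for sequence alignment")
  }
  sub <- Biostrings::nucleotideSubstitutionMatrix(
    match = scoring$match, mismatch = scoring$mismatch)
  al <- Biostrings::pairwiseAlignment(
    s1, s2, type = "global", substitutionMatrix = sub,
    gapOpening = abs(scoring$gap_open) - abs(scoring$gap_extend),
    gapExtension = abs(scoring$gap_extend))
  p <- strsplit(as.character(Biostrings::alignedPattern(al)), "")[[1]]
  q <- strsplit(as.character(Biostrings::alignedSubject(al)), "")[[1]]
  sum(p == q & p != "-") / length(p)
}

#' Mean pairwise sequence identity within communities
#'
#' All OTU pairs within a community are globally aligned (Needleman-Wunsch
#' with affine gaps under `scoring`); identity is identical aligned
#' positions over the full alignment length (gap columns count), averaged
#' over the community's pairs. Size-1 communities get NA.
#'
#' @param part A `coocc_partition`.
#' @param seqs A representative-sequence tibble (`otu_id`, `sequence`).
#' @param scoring An [alignment_scoring()].
#' @return A tibble: `community_id`, `n_otus`, `mean_identity`.
#' @export
mean_pairwise_identity <- function(part, seqs, scoring = alignment_scoring()) {
  if (!all(part$otu_id %in% seqs$otu_id)) {
    abort("sequences missing for some partition OTUs")
  }
  sq <- setNames(seqs$sequence, seqs$otu_id)
  groups <- split(part$otu_id, part$community_id)
  rows <- imap(groups, function(otus, cid) {
    if (length(otus) < 2) {
      return(tibble(community_id = as.integer(cid), n_otus = length(otus),
                    mean_identity = NA_real_))
    }
    idx <- combn(length(otus), 2)
    ids <- map_dbl(seq_len(ncol(idx)), function(j) {
      pair_identity(sq[[otus[idx[1, j]]]], sq[[otus[idx[2, j]]]], scoring)
    })
    tibble(community_id = as.integer(cid), n_otus = length(otus),
           mean_identity = mean(ids))
  })
  arrange(list_rbind(rows), .data$community_id)
}

#' Correlation of OTU abundance with parent community size
#'
#' Spearman correlation (two-tailed) between each partitioned OTU's mean
#' relative abundance across samples and the size of the community it
#' belongs to.
#'
#' @param t A count-table tibble.
#' @param part A `coocc_partition` with >= 3 OTUs.
#' @return A one-row tibble: `rho`, `p`, `n_otus` (NA sentinels when all
#'   community sizes are equal).
#' @export
abundance_size_correlation <- function(t, part) {
  if (nrow(part) < 3) abort("need at least 3 partitioned OTUs")
  r <- count_matrix(relative_abundance(t))
  if (!all(part$otu_id %in% colnames(r))) {
    abort("partition contains OTUs absent from the count table")
  }
  mean_ab <- colMeans(r)[part$otu_id]
  sizes <- table(part$community_id)[as.character(part$community_id)]
  sizes <- as.numeric(sizes)
  if (length(unique(sizes)) == 1) {
    return(tibble(rho = NA_real_, p = NA_real_, n_otus = nrow(part)))
  }
  ct <- suppressWarnings(cor.test(mean_ab, sizes, method = "spearman",
                                  exact = FALSE))
  tibble(rho = unname(ct$estimate), p = ct$p.value, n_otus = nrow(part))
}
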