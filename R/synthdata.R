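# Synthetic data with known ground truth: compositional count tables with
# planted co-occurrence blocks (latent Gaussian copula, log-normal
# marginals, multinomial sampling), planted-partition graphs, and power-law
# degree fixtures. These define the study conditions every pipeline stage
# is tested under.

#' Specification of a planted-block count table
#'
#' Latent log-abundances are multivariate normal with an equicorrelated
#' block-diagonal correlation structure (`rho_within` inside each block,
#' 0 elsewhere), exponentiated, normalised per sample, and sampled
#' multinomially at a per-sample depth uniform over `depth_range`. The
#' latent (basis) correlation inside a block is therefore known exactly,
#' which is what the SparCC recovery tests need.
#'
#' @param n_samples Number of samples.
#' @param block_sizes Integer vector of planted block sizes (each >= 2).
#' @param n_background_otus Independent background OTUs (exercise the
#'   prevalence filter and FDR calibration).
#' @param rho_within Latent within-block correlation in \[0, 1).
#' @param depth_range Min/max sequencing depth (counts per sample).
#' @param lognormal_mu_sd Mean and sd of the latent log-abundance scale.
#' @param seed Integer seed.
#' @return A `block_spec` list.
#' @export
block_spec <- function(n_samples = 400, block_sizes = rep(12, 4),
                       n_background_otus = 60, rho_within = 0.7,
                       depth_range = c(10000, 20000),
                       lognormal_mu_sd = c(0, 1), seed = 1) {
  stopifnot(all(block_sizes >= 2), rho_within >= 0, rho_within < 1,
            depth_range[1] >= 1, depth_range[2] >= depth_range[1])
  structure(list(n_samples = n_samples, block_sizes = block_sizes,
                 n_background_otus = n_background_otus,
                 rho_within = rho_within, depth_range = depth_range,
                 lognormal_mu_sd = lognormal_mu_sd, seed = seed),
            class = "block_spec")
}

#' Simulate a compositional count table with planted blocks
#'
#' @param spec A [block_spec()].
#' @return A list: `table` (count-table tibble) and `truth` (list with
#'   `blocks` tibble `otu_id`/`block` (0 = background), `correlation` the
#'   latent correlation matrix, `latent` the realised latent Gaussian
#'   matrix, `kept_otus` = all OTUs here).
#' @export
simulate_block_table <- function(spec) {
  stopifnot(inherits(spec, "block_spec"))
  nb <- length(spec$block_sizes)
  D <- sum(spec$block_sizes) + spec$n_background_otus
  block <- c(rep(seq_len(nb), spec$block_sizes),
             rep(0L, spec$n_background_otus))
  ids <- sprintf("otu%03d", seq_len(D))
  rho <- spec$rho_within
  Sigma <- diag(D)
  for (bk in seq_len(nb)) {
    i <- which(block == bk)
    Sigma[i, i] <- rho
    diag(Sigma)[i] <- 1
  }
  dimnames(Sigma) <- list(ids, ids)
  mu <- spec$lognormal_mu_sd[1]; s <- spec$lognormal_mu_sd[2]
  with_seed(spec$seed, {
    # equicorrelated blocks: z = sqrt(rho) * shared + sqrt(1 - rho) * own
    Z <- matrix(rnorm(spec$n_samples * D), spec$n_samples, D)
    if (rho > 0) {
      for (bk in seq_len(nb)) {
        i <- which(block == bk)
        shared <- rnorm(spec$n_samples)
        Z[, i] <- sqrt(rho) * shared + sqrt(1 - rho) * Z[, i]
      }
    }
    ab <- exp(mu + s * Z)
    frac <- ab / rowSums(ab)
    depths <- round(runif(spec$n_samples, spec$depth_range[1],
                          spec$depth_range[2]))
    counts <- t(vapply(seq_len(spec$n_samples), function(si) {
      as.integer(rmultinom(1, depths[si], frac[si, ]))
    }, integer(D)))
    dimnames(counts) <- list(sprintf("s%04d", seq_len(spec$n_samples)), ids)
    colnames(Z) <- ids
    list(table = as_count_table(counts),
         truth = list(blocks = tibble(otu_id = ids, block = block),
                      correlation = Sigma, latent = Z, kept_otus = ids))
  })
}

#' Simulate replicate datasets sharing one planted structure
#'
#' Draws `n_datasets` tables from the same latent block structure, each
#' with independent sampling noise and an independent random OTU dropout
#' mask — emulating cohorts that share underlying ecology but differ in
#' which OTUs were observed.
#'
#' @param spec A [block_spec()].
#' @param n_datasets Number of datasets.
#' @param dropout Per-OTU dropout probability per dataset, in \[0, 1).
#' @param seed Integer seed (overrides `spec$seed` for the family).
#' @return A list of `n_datasets` lists as in [simulate_block_table()],
#'   each `truth$kept_otus` recording the dataset's surviving OTUs.
#' @export
simulate_replicate_datasets <- function(spec, n_datasets, dropout = 0.1,
                                        seed = spec$seed) {
  stopifnot(dropout >= 0, dropout < 1)
  seeds <- derive_seeds(seed, 2 * n_datasets)
  map(seq_len(n_datasets), function(k) {
    sp <- spec
    sp$seed <- seeds[k]
    sim <- simulate_block_table(sp)
    kept <- with_seed(seeds[n_datasets + k], {
      sim$truth$blocks$otu_id[runif(nrow(sim$truth$blocks)) >= dropout]
    })
    sim$table <- sim$table[, c("sample_id", kept)]
    sim$truth$kept_otus <- kept
    sim
  })
}

#' Planted-partition (stochastic block model) graph
#'
#' @param sizes Community sizes.
#' @param p_in Within-community edge probability (> `p_out`).
#' @param p_out Between-community edge probability.
#' @param seed Integer seed.
#' @return A list: `network` (`coocc_network`, isolated nodes absent) and
#'   `truth` (`coocc_partition` over all generated nodes).
#' @export
planted_partition_graph <- function(sizes, p_in, p_out, seed = 1) {
  stopifnot(p_in > p_out)
  nb <- length(sizes)
  pm <- matrix(p_out, nb, nb); diag(pm) <- p_in
  g <- with_seed(seed, igraph::sample_sbm(sum(sizes), pref.matrix = pm,
                                          block.sizes = sizes))
  ids <- sprintf("n%03d", seq_len(sum(sizes)))
  el <- igraph::as_edgelist(g, names = FALSE)
  net <- new_network(tibble(otu_a = ids[el[, 1]], otu_b = ids[el[, 2]],
                            sign = 1L))
  truth <- new_partition(setNames(rep(seq_len(nb), sizes), ids))
  list(network = net, truth = truth)
}

#' Power-law degree fixture
#'
#' Constructs a degree sequence with counts proportional to `k^exponent`
#' over degrees 1..`k_max`, adjusts parity/graphicality minimally, and
#' realises it as a simple graph (deterministic realisation plus seeded
#' double-edge swaps).
#'
#' @param n_nodes Approximate number of nodes.
#' @param exponent Power-law exponent (< -1), e.g. -2.
#' @param seed Integer seed.
#' @param k_max Largest degree (default `round(sqrt(n_nodes))`).
#' @return A list: `degrees` (the realised sequence) and `network`.
#' @export
power_law_degree_fixture <- function(n_nodes, exponent = -2, seed = 1,
                                     k_max = max(5L, round(sqrt(n_nodes)))) {
  stopifnot(exponent < -1, n_nodes >= 10)
  k <- seq_len(k_max)
  w <- k^exponent
  nk <- round(n_nodes * w / sum(w))
  nk[nk < 1 & k <= k_max] <- pmax(nk[nk < 1], 1)
  degrees <- rep(k, nk)
  for (attempt in 1:50) {
    if (sum(degrees) %% 2 == 1) degrees <- c(degrees, 1L)
    if (igraph::is_graphical(degrees)) break
    degrees <- degrees[-which.max(degrees)]
    if (attempt == 50) abort("could not build a graphical power-law sequence")
  }
  net <- random_graph_from_degree_sequence(degrees, seed = seed)
  list(degrees = as.integer(degrees), network = net)
}

#' Synthetic representative sequences for planted blocks
#'
#' One random root sequence per block; members are copies mutated at rate
#' `within_block_divergence`, so within-block identity is high by
#' construction. Background OTUs get independent random sequences.
#'
#' @param truth A `truth` list from [simulate_block_table()].
#' @param seed Integer seed.
#' @param length Sequence length (default 150).
#' @param within_block_divergence Per-base substitution rate inside a block.
#' @return A tibble: `otu_id`, `sequence`.
#' @export
simulate_rep_seqs <- function(truth, seed = 1, length = 150,
                              within_block_divergence = 0.03) {
  bases <- c("A", "C", "G", "T")
  blocks <- truth$blocks
  with_seed(seed, {
    roots <- map(unique(blocks$block[blocks$block > 0]), ~
                   sample(bases, length, replace = TRUE))
    names(roots) <- unique(blocks$block[blocks$block > 0])
    seqs <- map_chr(seq_len(nrow(blocks)), function(i) {
      b <- blocks$block[i]
      if (b == 0) return(paste(sample(bases, length, replace = TRUE),
                               collapse = ""))
      s <- roots[[as.character(b)]]
      mut <- runif(length) < within_block_divergence
      s[mut] <- sample(bases, sum(mut), replace = TRUE)
      paste(s, collapse = "")
    })
    tibble(otu_id = blocks$otu_id, sequence = seqs)
  })
}

#' Synthetic per-sample metadata
#'
#' Age, BMI and sex drawn from plausible adult-cohort distributions; depth
#' taken from the count table.
#'
#' @param t A count-table tibble.
#' @param seed Integer seed.
#' @return A metadata tibble (`sample_id`, `age`, `bmi`, `sex`, `depth`).
#' @export
simulate_metadata <- function(t, seed = 1) {
  depths <- sample_depths(t)
  with_seed(seed, {
    n <- nrow(depths)
    tibble(sample_id = depths$sample_id,
           age = round(pmax(18, rnorm(n, 50, 12)), 1),
           bmi = round(pmax(15, rnorm(n, 25, 4)), 1),
           sex = sample(c("male", "female"), n, replace = TRUE),
           depth = depths$depth)
  })
}
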