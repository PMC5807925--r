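test_that("count tables round-trip through TSV and reject invalid input", {
  t <- toy_counts()
  f <- withr::local_tempfile(fileext = ".tsv")
  write_count_table(t, f)
  expect_equal(read_count_table(f), t)

  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample_id\to1\to2", "s1\t3\t-1"), bad)
  expect_error(read_count_table(bad), "negative")

  dup <- t
  dup$sample_id <- c("s1", "s1", "s3")
  expect_error(validate_count_table(dup), "duplicate")
})

test_that("BIOM tables are read in the samples-by-OTUs orientation", {
  skip_if_not_installed("biomformat")
  m <- matrix(c(5L, 0L, 3L, 2L, 1L, 4L), 2, 3,
              dimnames = list(c("o1", "o2"), c("s1", "s2", "s3")))
  f <- withr::local_tempfile(fileext = ".biom")
  biomformat::write_biom(biomformat::make_biom(m), f)
  t <- read_count_table(f, format = "biom")
  expect_equal(count_matrix(t), t(m) * 1.0, ignore_attr = FALSE)
})

test_that("TSV orientation is handled, including auto-detection", {
  t <- toy_counts()
  f <- withr::local_tempfile(fileext = ".tsv")
  m <- count_matrix(t)
  readr::write_tsv(tibble::tibble(otu_id = colnames(m),
                                  tibble::as_tibble(t(m))), f)
  expect_equal(read_count_table(f, orientation = "otus"), t)
  expect_equal(read_count_table(f, orientation = "auto",
                                sample_ids = t$sample_id), t)
})

test_that("quality filters apply the depth-then-occupancy rules", {
  out <- filter_low_quality(filter_toy())
  expect_setequal(out$sample_id, c("s1", "s3", "s4"))
  expect_setequal(setdiff(names(out), "sample_id"), c("o1", "o3", "o5"))
  # boundary: a sample at exactly the threshold is retained
  expect_true("s4" %in% out$sample_id)
  # idempotent
  expect_equal(filter_low_quality(out), out)
  expect_error(filter_low_quality(toy_counts(), min_sample_depth = 1e6),
               "all samples")
})

test_that("prevalence filter is inclusive at the boundary and idempotent", {
  m <- matrix(0L, nrow = 4, ncol = 3,
              dimnames = list(paste0("s", 1:4), c("a", "b", "c")))
  m[1, "a"] <- 5L          # occupancy 1/4 = 25%
  m[, "b"] <- 2L           # occupancy 4/4
  m[1:2, "c"] <- 0L        # occupancy 0
  m[1, "c"] <- 0L
  t <- as_count_table(m)
  out <- prevalence_filter(t, 0.25)
  expect_setequal(setdiff(names(out), "sample_id"), c("a", "b"))
  expect_equal(prevalence_filter(out, 0.25), out)
  out10 <- prevalence_filter(t, 0.26)
  expect_setequal(setdiff(names(out10), "sample_id"), "b")
})

test_that("rarefaction subsamples without replacement, reproducibly", {
  t <- toy_counts()
  r1 <- rarefy(t, 5, seed = 42)
  r2 <- rarefy(t, 5, seed = 42)
  expect_identical(r1, r2)
  expect_true(all(rowSums(count_matrix(r1)) == 5))
  expect_true(all(count_matrix(r1) <= count_matrix(t)))
  expect_error(rarefy(t, 100, seed = 1), "s1")

  # hypergeometric mean: E[rarefied count] = depth * count / total
  m <- matrix(c(60L, 30L, 10L), 1, dimnames = list("s", c("a", "b", "c")))
  tt <- as_count_table(m)
  draws <- vapply(1:1000, function(s) count_matrix(rarefy(tt, 20, seed = s))[1, ],
                  numeric(3))
  expected <- 20 * c(60, 30, 10) / 100
  se <- sqrt(20 * (c(60, 30, 10) / 100) * (1 - c(60, 30, 10) / 100) *
               (100 - 20) / 99) / sqrt(1000)
  expect_true(all(abs(rowMeans(draws) - expected) < 3 * se))
})

test_that("relative abundance normalises rows and is scale-invariant", {
  m <- matrix(c(2L, 2L, 1L, 3L), 2, byrow = TRUE,
              dimnames = list(c("s1", "s2"), c("a", "b")))
  r <- relative_abundance(as_count_table(m))
  expect_equal(unlist(r[1, c("a", "b")], use.names = FALSE), c(0.5, 0.5))
  expect_true(all(abs(rowSums(count_matrix(r)) - 1) < 1e-9))
  r2 <- relative_abundance(as_count_table(m * 7L))
  expect_equal(count_matrix(r2), count_matrix(r))
  z <- as_count_table(matrix(c(0L, 0L), 1, dimnames = list("s", c("a", "b"))))
  expect_error(relative_abundance(z), "zero-total")
})

test_that("alpha diversity matches analytic values and bounds", {
  # uniform 4-OTU sample: rarefaction at the full depth is exact
  u <- as_count_table(matrix(rep(2500L, 4), 1,
                             dimnames = list("s", paste0("o", 1:4))))
  inv <- alpha_diversity(u, "inv_simpson", depth = 10000, n_reps = 3, seed = 1)
  expect_equal(inv$value, 4)
  sh <- alpha_diversity(u, "shannon", depth = 10000, n_reps = 3, seed = 1)
  expect_equal(sh$value, log(4))

  one <- as_count_table(matrix(c(500L, 0L), 1, dimnames = list("s", c("a", "b"))))
  expect_equal(alpha_diversity(one, "shannon", depth = 500, n_reps = 2,
                               seed = 1)$value, 0)
  expect_equal(alpha_diversity(one, "inv_simpson", depth = 500, n_reps = 2,
                               seed = 1)$value, 1)

  # deep two-OTU 50/50 sample: shannon close to ln 2 under rarefaction noise
  deep <- as_count_table(matrix(c(50000L, 50000L), 1,
                                dimnames = list("s", c("a", "b"))))
  sh2 <- alpha_diversity(deep, "shannon", depth = 10000, n_reps = 10, seed = 7)
  expect_lt(abs(sh2$value - log(2)), 0.001)

  # bounds on arbitrary samples
  sim <- simulate_block_table(block_spec(n_samples = 10, block_sizes = c(3, 3),
                                         n_background_otus = 6,
                                         depth_range = c(2000, 3000), seed = 5))
  d <- ncol(count_matrix(sim$table))
  inv <- alpha_diversity(sim$table, "inv_simpson", depth = 2000, n_reps = 2,
                         seed = 2)
  expect_true(all(inv$value >= 1 & inv$value <= d))
  sh <- alpha_diversity(sim$table, "shannon", depth = 2000, n_reps = 2, seed = 2)
  expect_true(all(sh$value >= 0 & sh$value <= log(d)))
})

test_that("sparsity counts zero cells", {
  m <- matrix(c(1L, 0L, 2L, 0L, 0L, 3L, 4L, 0L, 5L, 6L, 0L, 7L), 3,
              dimnames = list(paste0("s", 1:3), paste0("o", 1:4)))
  expect_equal(sparsity(as_count_table(m)), 5 / 12)
  expect_equal(sparsity(as_count_table(m + 1L)), 0)
})

test_that("metadata, taxonomy and FASTA readers validate their inputs", {
  md <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample_id\tage\tbmi\tsex\tdepth",
               "s1\t40\t22.5\tMale\t12000",
               "s2\t55\t30.1\tNA\t15000"), md)
  d <- read_sample_metadata(md)
  expect_equal(d$sex, c("male", "unknown"))

  fa <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">o1 desc", "ACGT", "ACGT", ">o2", "GGGC"), fa)
  s <- read_rep_seqs(fa)
  expect_equal(s$sequence, c("ACGTACGT", "GGGC"))
  expect_equal(s$otu_id, c("o1", "o2"))
})
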