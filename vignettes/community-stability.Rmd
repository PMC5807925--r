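---
title: "Methods: ensemble co-occurrence networks and stable communities"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ensemble co-occurrence networks and stable communities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its statistical methodology: the
models, the parameters that matter, the numerical choices, and what the
synthetic benchmarks do and do not establish.

## Why an ensemble, and why these four estimators

OTU counts are compositional: a sample's counts are informative only
relative to its sequencing depth, so an increase in one abundant taxon
depresses every other relative abundance and induces spurious negative
correlation. They are also sparse (typically about half the cells are
zero). No single correlation estimator is reliable under both problems, so
the package combines four with complementary failure modes — Pearson and
Spearman on relative abundances (fast, well-understood, but
compositionally biased), a SparCC-style basis-correlation estimator
(explicitly models compositionality), and a CoNet-style ensemble whose
ReBoot null preserves compositional artefacts while destroying pairwise
association — and only keeps an edge when all four agree on its direction
and significance. The intersection trades recall for precision: every edge
that survives is supported by four disagreeing models of the data.

## Table preparation

Samples with fewer than 10,000 total counts are removed, then OTUs present
in fewer than two samples. Correlation estimation additionally restricts
to OTUs present in at least 25% of samples (inclusive boundary; "at least"
is taken literally), computed on the raw, unrarefied table — prevalence is
a property of the observed data, not of a resampled version. Rarefaction
(used only for diversity) subsamples without replacement to a fixed depth;
Shannon diversity uses natural logarithms throughout the package because
the variation-of-information normalisation below is also in nats
(`alpha_diversity(base = )` changes this). Diversity indices are averaged
across ten rarefactions by default.

## SparCC-style estimation

With fractions x_i, the log-ratio variance t_ij = Var log(x_i/x_j)
relates to latent ("basis") variances ω² and correlations ρ by
t_ij = ω_i² + ω_j² − 2 ρ_ij ω_i ω_j. Assuming most ρ_ij ≈ 0, row sums of
t give the linear system Σ_{j≠i} t_ij = (D−2) ω_i² + Σ_j ω_j², solved
directly. Strong pairs violate the assumption, so after solving, the
single largest |ρ| ≥ 0.1 pair is removed from the row sums and the system
re-solved, up to 10 times (pairs are excluded from the sums; OTUs are
never removed). Fractions are Dirichlet posterior draws with a +1 prior
(so zeros never enter a log), and the reported matrices are elementwise
medians over 20 draws. Choices worth noting:

* An exclusion threshold ≥ 1 disables exclusion altogether; clipped
  ρ = ±1 values would otherwise be "excluded" at threshold exactly 1,
  which would break the identity between the no-exclusion configuration
  and the plain estimator.
* Solved basis variances can come out non-positive when the sparsity
  assumption is badly violated; they are floored at 10⁻¹² with a warning
  rather than propagated as NaN.
* Pseudo p-values permute each OTU's counts independently across samples
  and re-run the full estimator per null table; p = (1 + k)/(B + 1) with
  k the count of null |ρ| at least as large. The add-one estimator never
  returns p = 0 — a deliberate deviation from implementations that can.
  Consequently p < 0.01 requires B ≥ 100 null tables; configurations with
  smaller B cannot clear strict thresholds, by design.
* The estimator needs D ≥ 4 OTUs (the linear system is under-determined
  below that).

## CoNet-style ensemble

Four measures are computed for every pair: Pearson, Spearman, Bray–Curtis
Σ|u−v| / Σ(u+v), and symmetrised Kullback–Leibler divergence between the
two OTUs' sample-normalised distributions (each vector rescaled to sum 1,
pseudocount 1/(2n) added, renormalised — the pseudocount is configurable).
Dissimilarities have inverted polarity: low values indicate co-presence.

Initial thresholds expand per-measure rank cutoffs in lock-step, one rank
per measure per step, until the set of pairs top-ranked by *all four*
measures reaches the configured targets (2,000 co-presence and 2,000
exclusion candidates at defaults) — equivalently, the smallest common
cutoff whose four-way intersection meets the target. Candidates ranked
into both sets are ambiguous and dropped with a warning.

Each candidate then receives a ReBoot p-value per measure: the two OTUs'
abundances are permuted independently across samples, every sample's
composition renormalised, and the measure recomputed; the two-sided
p-value counts null scores at least as far from the null mean as the
observed, with add-one smoothing. One permutation stream per pair is
shared across the four measures (they are all functions of the same
permuted pair, and sharing quarters the cost without coupling distinct
pairs). Direction is sign(observed − null mean) mapped through each
measure's polarity, so +1 always means co-presence; edges whose four
directions disagree are dropped.

The original CoNet's internal bootstrap screen is not described in the
source material for this design; the package implements a stated
approximation: n_bootstraps resamples of samples with replacement give the
observed score's bootstrap distribution per measure, and the edge is
dropped when the ReBoot null mean falls inside the central 95% interval
for any measure (an edge that cannot be told from its own null under
resampling noise is unstable). Per-edge p-values are merged by their
minimum — exactly "keep the minimum", not textbook Simes — and BH FDR is
applied across retained edges.

## Intersection and threshold selection

An edge enters the ensemble network only if present in all four edge
tables with identical direction and adjusted p strictly below the
threshold ("below" is read as strict `<`; the boundary case is excluded).
The sweep evaluates 0.05 and then 10⁻² through 10⁻⁸ — eight thresholds —
and scores each network's degree distribution against a power law: degrees
are binned into 10 equal-width bins, and log₁₀(node fraction) is regressed
on log₁₀(mean degree) per non-empty bin; R² > 0.8 with slope near −2
indicates scale-free structure. Equal-width (not logarithmic) binning
follows the fit-index procedure this mirrors; `n_breaks` is configurable.
Networks with a single distinct degree return NA sentinels rather than
errors, as do empty networks, so a sweep never aborts mid-ladder.

Nodes exist only through edges: an OTU with no surviving edge is not part
of the network, and mean path length averages over connected pairs only
(ensemble networks are not guaranteed connected; excluding unreachable
pairs keeps the statistic finite without arbitrarily imputing
infinities). Negative edges — consistently below 1% after intersection —
are removed before community detection, dropping any node left isolated.

## Community detection and the γ sweep

Modularity is the unweighted generalised form
Q = (1/2m) Σ_ij (A_ij − γ k_i k_j/2m) δ(c_i,c_j); the networks are
unweighted after intersection, so no weighted variant is needed. γ scales
the null term: small γ yields few large communities, large γ many small
ones (community count is empirically non-decreasing in γ on the fixture
networks). Louvain (greedy local moves plus aggregation) with a seeded
run order maximises Q; igraph's implementation is used behind the
package's interface, with Q recomputed by the package's own formula so
the reported value is self-consistent with `modularity_q()` (which is
validated against exhaustive partition enumeration in the tests).

γ is chosen by running the sweep (0.1–1 in steps of 0.01 by default):

* **Stability**: 25 runs per γ; mean pairwise 1 − VI/ln N between runs
  (1 = every run identical).
* **Significance**: modularity of the real network versus one Louvain run
  on each of 100 random graphs with exactly the real degree sequence,
  built by a deterministic graphical realisation followed by 10·E seeded
  double-edge swaps. The random graphs are generated once per sweep and
  reused across γ values — the comparison at each γ needs the same null
  ensemble, not a fresh one, and this keeps the sweep tractable.

The final partition at the chosen γ is the best-modularity result of 100
runs (ties broken by earliest run).

## Comparing and mapping communities across datasets

Two partitions are compared on their shared OTUs only:
VI = H(a) + H(b) − 2 I(a;b) in nats, normalised by ln(shared count) so
1 − nVI ∈ [0,1]. Normalising by the shared-node count (rather than either
network's full size) makes each pairwise comparison a self-contained
universe — the shared subset is the operative network. The permutation
null shuffles both partitions' node labels (community-size multisets
preserved) and reports the null mean, sd and maximum of the similarity;
an observed similarity above the null maximum at 1,000 permutations is
the replication criterion.

Individual communities are matched by Jaccard index with a strict > 0.25
threshold. A community-type is a set of matched communities, exactly one
per dataset, connected across all datasets; communities matching more
than one community in the same other dataset are diagnostic-flagged and
excluded from type formation (the 0.25 threshold exists precisely because
multiple mapping vanishes above it). Types are labelled from a fixed,
ordered 30-colour vocabulary in descending mean-Jaccard order, so
labelling is deterministic.

## Community profiles and host associations

Community abundance in a sample is the sum of member-OTU counts over the
sample's total counts (all OTUs, including those outside the network, so
community values need not sum to 1). Associations regress
log₁₀(abundance + 10⁻⁶) on BMI + age + sex + depth by OLS, with sex a
categorical covariate keeping "unknown" as a level (dropping unknowns
would discard whole samples), listwise deletion of missing covariates,
raw-unit (unstandardised) covariates, and BH FDR per phenotype across the
non-degenerate communities. Mean pairwise identity aligns member
sequences globally under match +1, mismatch −1, gap open −2, gap extend
−1; a length-L gap costs −2 − (L−1) — the first gapped position carries
the opening penalty — and identity divides identical aligned positions by
the full alignment length including gap columns (the conservative
denominator; the alternative, dividing by the shorter sequence length,
can exceed estimates users expect from global alignments).

## Synthetic data: what it emulates and what it does not

`simulate_block_table()` draws latent log-abundances from an
equicorrelated block-diagonal Gaussian (correlation ρ_within inside each
planted block), exponentiates to log-normal abundances, normalises per
sample, and draws multinomial counts at a depth uniform on
10,000–20,000. The latent Gaussian copula was chosen over a
Dirichlet-multinomial precisely because it fixes a known pairwise basis
correlation for recovery tests. Background OTUs are independent so
prevalence filtering and FDR calibration are exercised against a true
null. Replicate cohorts share one latent structure, with independent
sampling noise and independent 10% OTU dropout per dataset.

What this does **not** emulate: real zero-inflation beyond multinomial
sampling, phylogenetically structured correlation, batch effects, or
negative ecological interactions (planted blocks are positive). Passing
benchmarks therefore demonstrate that the pipeline recovers the structure
it models under realistic depth and sparsity, not that any particular
real dataset satisfies those assumptions.

## Benchmark design choices and problem sizes

The validation suite and `scripts/acceptance.R` run at sizes chosen to
make the statistics meaningful on a single CPU:

* SparCC recovery uses four blocks of 5 among 50 OTUs at n = 500. Small
  blocks keep the total correlated mass consistent with the estimator's
  own sparsity assumption; with 48 of 50 OTUs correlated the assumption
  is globally violated and background pairs absorb bias — a property of
  the model, not a bug, and the reason heavily structured tables should
  be interpreted through the ensemble rather than SparCC alone.
* The cross-cohort replication benchmark uses three cohorts of 250
  samples, four planted blocks of 12 among 60 background OTUs, 10%
  dropout; SparCC pseudo p-values use 100 null tables (the minimum that
  can clear p < 0.01 under add-one smoothing) and ReBoot uses 300
  permutations with candidate targets of 250/100 — scaled to this table's
  pair count the way the 2,000/2,000 defaults are scaled to
  cohort-sized tables.
* Null calibration uses 30-OTU, 100-sample tables with no planted
  structure; the four-way p < 0.01 intersection is expected to contain
  at most 1% of pairs (observed: essentially zero).
* A γ of 0.4 is used for the benchmark partitions, in the stable and
  significant mid-range identified by the sweep on these fixtures.

## Known limitations

* The CoNet component is faithful to the described procedure
  (permutation + renormalisation null, bootstrap screen, minimum-p merge,
  BH), not bit-faithful to the original tool's pooled z-score machinery.
* SparCC pseudo p-values are granular at 1/(B+1); strict thresholds
  require proportionally many null tables, which dominates runtime.
* Lock-step threshold expansion assumes the four measures' rankings are
  comparable rank-by-rank; with pathological score ties the candidate
  set at the stopping cutoff can slightly exceed the target.
* VI-based comparisons say nothing about OTUs not shared between
  networks; a high similarity on a small shared set is a weaker statement
  than the same similarity on a large one (the shared count is always
  reported alongside).
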