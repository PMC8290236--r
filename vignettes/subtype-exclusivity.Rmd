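---
title: "Subtype-conditioned mutual exclusivity of driver gene mutations: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Subtype-conditioned mutual exclusivity: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its science: the models, the
tunable parameters and why their defaults are what they are, what the
synthetic-cohort generator does and does not emulate, the numerical
choices, and the known limitations. It states no empirical result that the
test suite does not itself compute.

## The problem

Two driver genes are *mutually exclusive* when fewer tumors carry both
mutations than expected under independence — a classic signal of pathway
redundancy. Carriers of one driver mutation are not homogeneous, though:
their transcriptomes fall into subtypes, and an exclusivity confined to one
subtype is diluted, often to invisibility, in a gene-level test. The
pipeline therefore (i) splits each driver gene's carriers into expression
subtypes, (ii) re-runs the exclusivity screen with subtype events as the
unit, (iii) annotates exclusive pairs and triples with the biological
functions their subtypes share, and (iv) asks whether exclusive triples
carry prognostic information.

## Subtype discovery

For each driver gene with more than `small_group_cutoff = 20` carriers:

* **Feature selection.** Genes are ranked by raw (unscaled) median
  absolute deviation across the gene's carriers and the top
  `n_top = 2000` kept; expression is `log2(x + 1)`-transformed (the +1
  because raw counts contain zeros; the source procedure does not state an
  offset) and median-centered per gene. MAD rather than variance because
  mutation-bearing cohorts have heavy-tailed expression.
* **Consensus PAM.** `n_iter = 1000` resampling iterations, each drawing
  `ceiling(0.8 n)` samples *without* replacement (samples only; features
  are never resampled), PAM on the Pearson distance `1 − r` at every `k`
  in `k_range = 2:6`. The consensus entry for a sample pair is
  co-clustered count / co-sampled count; pairs never co-sampled are set to
  0.5 (maximally ambiguous) with a warning.
* **Choosing k.** The source procedure chose k by reading consensus
  membership heatmaps. The automated stand-in is PAC — the fraction of
  off-diagonal consensus entries strictly between 0.1 and 0.9 — minimized
  over `k_range`, except that the smallest k within `pac_tol = 0.01` of
  the minimum wins. The tolerance exists because a strict argmin lets a
  large k beat k = 2 on a sub-0.01 PAC difference produced by resampling
  noise and nested co-carrier substructure; a human reading the heatmap
  would never make that choice.
* **Labels** come from average-linkage hierarchical clustering of
  1 − consensus cut at the chosen k, so the final partition derives from
  the consensus, not from any single PAM run.
* **Pruning.** Silhouette widths `s = (b − a)/max(a, b)` on the Pearson
  distance, one pass; samples with `s ≤ 0` are removed (members of
  singleton clusters have `s` defined as 0 and are removed); subtypes left
  with fewer than `min_subtype_size = 5` members are dropped entirely.
  Retained subtypes are renumbered S1, S2, ... by decreasing size.

Genes with ≤ 20 carriers skip the resampling and are split once by PAM at
k = 2, then pruned identically.

PAM itself is BUILD + best-improvement SWAP. SWAP is a local search, and on
small adversarial instances single-start BUILD+SWAP (including the
canonical `cluster::pam`) misses the global optimum several percent of the
time; `pam_cluster()` therefore runs three deterministic starts (the first
BUILD medoid forced to each of the three points with smallest distance
sums) and keeps the best local optimum — measured to remove all misses on
1000 random small instances. Ties break toward the smallest index
everywhere, so results depend only on the distance matrix.

## The exclusivity test

The background model is the maximum-entropy distribution over independent
Bernoulli entries that matches every observed row (event) and column
(sample) margin: `p_ij = logistic(μ_i + λ_j)`. It is fitted by alternating
vectorized Newton sweeps on μ and λ until every expected margin is within
`tol = 1e-6` of the observed one; all-zero/all-one rows and columns are
pinned to 0/1 and excluded (iteratively, until stable). Because λ absorbs
per-sample mutation load, a sample with many mutations is *expected* to
overlap more, which is what separates genuine exclusivity from load
artifacts.

Two estimation details matter in practice:

* **λ comes from the full mutation profile.** With only a dozen driver
  events, per-sample load estimates are so noisy that expected overlaps
  are biased upward (a Jensen effect through the noisy λ), and the test
  becomes anticonservative — the measured null type-I error was ~0.14 at
  nominal 0.05. The pipeline therefore fits λ on the matrix of *all*
  mutated genes in the MAF (as genome-wide load estimation does) and then
  fits each tested event's μ with λ frozen, via `extend_background()`.
  With this scheme the null fraction of p < 0.05 sits inside the binomial
  99% CI of 0.05 (test suite, criterion 3).
* **Subtype events reuse the gene-level λ.** Mutation load is a property
  of samples, not of events; refitting λ against the disjoint subtype rows
  of one gene would distort it. Each subtype row gets its own μ so its
  expected row sum matches its carrier count.

The test statistic for a pair is the observed overlap `o`; under the
background, the overlap is Poisson-binomial with per-sample probability
`p_aj p_bj`. The CDF is computed by exact dynamic programming over the
first `o + 1` states (O(n·o), stable to n = 10^4; small counts dominate,
so no normal approximation is used). Mutual exclusivity is the lower tail
`P(X ≤ o)`, co-occurrence the upper tail; the two one-sided families are
BH-corrected separately (the threshold `q < 0.05` is configurable).
Subtype events of one gene are disjoint by construction — structural, not
biological, exclusivity — so same-gene pairs are refused. Exclusive
triples are triangles of significant ME pairs whose events come from three
distinct genes.

The exact tail makes the test conservative where overlap counts are small
(discreteness) and where rates are high (margin conditioning shrinks the
overlap variance below the Poisson-binomial's); it is never
anticonservative once λ is stable. This is a real property of the method
family, documented rather than patched.

## Functions of pairs and triples

Expression is filtered to genes with counts > 1 in at least 30% of
samples. Differential expression of a subtype's members against wild-type
samples (no non-silent mutation in that gene — a single shared definition
used by both the DE and survival modules) uses a per-gene NB model:
median-of-ratios size factors (library-size fallback when too few genes
are all-positive), pooled method-of-moments dispersion floored at 1e-8,
IRLS with log link and size-factor offset, and a two-sided Wald test on
the group coefficient. DEGs are `|log2FC| ≥ 1` and BH `q < 0.05`. This
replaces the cited external DE tool with a defined, testable equivalent of
the same model class; the suite checks both null calibration and ≥ 90%
sensitivity at `|log2FC| = 2`.

Enrichment is the one-sided hypergeometric upper tail of each gene-set
term against the DEG list, terms restricted to effective sizes in
`[5, 2000]` (standard bounds; giant terms are trivially "significant"),
BH across terms, `q < 0.05`. The cited enrichment service's proprietary
correction is replaced by BH — a documented divergence. A pair's function
set is the intersection of its two members' significant terms (the
functional-redundancy reading of exclusivity); a triple's is any term in
at least two of its three pair sets.

## Survival

A triple's carriers are the union of its three subtype member sets;
the comparator is wild-type for all three genes. Samples mutated in a
triple gene but pruned from its subtype belong to neither group (an
`include_pruned` switch restores them to the carriers). Kaplan-Meier and
the two-group log-rank test are implemented directly (hypergeometric
variance, χ² on 1 df); Cox models are fitted through `survival::coxph`
(partial-likelihood Newton, Breslow ties by default, Efron by option) with
separation/non-convergence surfaced as flags rather than silent numbers.
The multivariate model adds age, gender and AJCC/T/N stage dummies against
baselines I/T1/N0, complete-case per model with n reported; absent stage
levels are dropped with a warning. "Independent predictor" means
multivariate carrier p < 0.05.

## The synthetic world

`sim_config()` defaults describe the stated world of the recovery tests:
300 samples, 2000 expression genes, 12 driver genes; per-sample log-load
multipliers N(0, 0.5); NB dispersions log-uniform on [0.02, 0.15]
(typical bulk RNA-seq); per-subtype DE blocks of 83 genes shifted by
log2-effect 2.0; planted mutual exclusivity with suppression ε = 0; one
co-occurrence pair (ρ = 3); one exclusive triple whose carriers have
hazard ratio 1.8 with ~30% censoring.

Three generator choices deserve explanation because they were forced by
coherence, not convenience:

* **A global transcriptomic program.** Each sample draws a latent program
  (two states, balanced); a gene's subtype label copies the program with
  fidelity 0.98, else is redrawn. Fully independent per-gene labels make
  label recovery impossible in principle: twelve genes would impose twelve
  independent partitions of overlapping carrier sets with equally strong
  DE blocks, and the conflicting structure caps ARI far below any useful
  threshold. Correlated subtype programs are also what real cohorts show —
  expression subtypes are tumor states, not per-mutation accidents. A
  consequence faithfully inherited from this structure: subtype events
  aligned to opposite programs are genuinely exclusive even without a
  planted directive, so a default cohort has many significant subtype
  pairs beyond the planted ones, exactly as the motivating study found
  hundreds.
* **High rates for exclusivity-planted genes.** A subtype-level signal is
  detectable only when both subtype events are large (expected pair
  overlap of order 10); genes in planted ME pairs and the triple draw
  carrier rates from [0.35, 0.45] (TP53/KRAS frequencies), all others
  from [0.08, 0.18]. A ρ-fold co-occurrence boost only fits a moderate
  baseline rate (ρ·p < 1), so CO genes stay in the background range.
* **Marginal-preserving suppression.** Removing gene B from subtype A.S1
  depletes specifically the A∩B joint; without compensation the *gene*
  pair becomes exclusive too, which is precisely what the subtype analysis
  claims does not happen. Removed carriers are therefore redistributed,
  85% into A's other subtypes and 15% elsewhere — the gene-level pair
  stays near independence (as in the real-data examples of subtype-level
  pairs with gene-level q ≈ 1) while the designated subtype keeps zero
  overlap. The 15% leak avoids an implausible carrier pile-up in the
  other subtype. For the planted triple, only the same-program edge needs
  an explicit suppression; the two cross-program edges are exclusive
  through the label correlation.

What the generator does **not** emulate: mutational signatures, copy
number, tumor purity, batch effects, more than one expression program
axis, and censoring that depends on covariates. A green recovery test
therefore establishes that the pipeline recovers the *kind* of structure
the method targets at realistic effect sizes — not that it would recover
any particular real cohort's biology.

## Numerical and procedural choices

* One master seed; every stochastic stage derives a child stream by
  hashing `(seed, stage, gene)`, so adding one gene never perturbs
  another's stream, and end-to-end reruns are byte-identical (checked by
  manifest checksums).
* Pairs are emitted in lexicographic event order; BH never reorders
  output.
* p-values are clamped away from exact 0 (`.Machine$double.xmin`) so
  downstream `log`/BH operations are safe.
* Degenerate inputs error loudly: empty driver lists, constant vectors
  under Pearson distance, groups of size < 2 in DE, empty comparator
  groups and all-censored endpoints in survival.
* Consensus scale in the shipped tests is reduced to 30–150 iterations
  (function default 1000) purely for compute budget; determinism and
  recovery do not depend on the scale, and the reduction is stated in the
  tests.

## Known limitations

* The exact Poisson-binomial screen is conservative for small expected
  overlaps; rare-gene pairs need larger cohorts, not looser thresholds.
* PAC-based k selection is an automated stand-in for a human heatmap
  read; its 0.01 tolerance is a judgment encoded as a constant.
* The NB Wald test with moment dispersion is anticonservative for very
  small groups (< ~10 per arm); the subtype-size floor of 5 is close to
  that edge, and borderline DE calls from tiny subtypes deserve caution.
* The wild-type definition ("no non-silent mutation in the gene(s) under
  test") does not exclude carriers of other drivers; a config override
  restricts wild-type to pan-driver-negative samples.
* Survival analysis ignores competing risks for disease-specific
  survival and does not test proportional hazards.
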