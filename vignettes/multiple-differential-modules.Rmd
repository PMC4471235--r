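---
title: "Finding multiple differential modules across condition-specific co-expression networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Finding multiple differential modules across condition-specific co-expression networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mdmnet)
```

## The problem

A disease study profiles the transcriptome under a healthy baseline and
several disease conditions (for example, genetic and surgical stress
models and their combination), each over a time course with replicates.
Two genes that are co-expressed *and* differentially expressed against
baseline in a condition likely act in a pathway whose activity changes
in that condition.  mdmnet builds one weighted **differential
co-expression network** (DCN) per disease condition and then looks for
gene modules that are coherent in one, several, or all of the networks
simultaneously.  A module found in exactly m networks is an *m-level
module*: level 1 means condition-specific biology, level 2 and above
means shared biology whose *wiring* may still differ between conditions
-- which a dedicated connectivity-dynamics statistic quantifies.

## Network construction

For each disease condition:

1. **Co-expression screen.**  A gene pair is a candidate edge when the
   absolute Pearson correlation of its expression profiles within that
   condition reaches the threshold `delta` (default 0.8, chosen in
   practice with `select_delta()` as the largest value that keeps the
   maximal number of genes connected in every network).  To remove
   *indirect* edges, the minimum absolute first-order partial
   correlation over all conditioning genes z is computed:
   a mediated chain x → z → y has partial correlation near 0 given z,
   while a pair that co-varies through a shared module factor retains a
   clearly non-zero partial (about r/(1+r) given another member).  A
   pair therefore passes when its marginal correlation reaches `delta`
   *and* its minimum partial correlation stays at or above `q_cut`
   (default 0.2, between those two regimes).  Requiring the partial
   correlation itself to reach `delta` would delete precisely the
   factor-driven modules the method is looking for.
2. **Differential weighting.**  A surviving edge (i, j) gets weight
   `sqrt(-log p_i - log p_j) / sqrt(2 max_l |log p_l|)` (natural logs),
   where `p_i` is gene i's differential-expression p-value against
   baseline (supplied as a table; any DE tool can produce it).  Weights
   lie in (0, 1]; the weight is 1 exactly when both endpoints attain
   the network's smallest p-value and 0 when neither gene is
   differential.  P-values below 1e-300 are clamped at load so the
   logarithms stay finite.

The M networks share one gene set, so they form a 3-way array of edge
weights; everything downstream works on that stack.

## Module search

**Seed ranking.**  In each network, gene importance is the stationary
point of `g = A'g` on the symmetrically normalised adjacency
`A' = D^(-1/2) A D^(-1/2)`: importance grows with the number, strength
and importance of a gene's neighbours.  On a connected graph this
stationary solution has a closed form -- the principal eigenvector of
`A'` is exactly the square root of a gene's total strength -- and the
package computes it directly (an iterative solver can take arbitrarily
long on graphs with dense blocks joined by single weak edges).  On a
graph with several components the eigenvalue-1 eigenspace is
degenerate and is resolved by continuity: `sqrt(strength)`, normalised
over the whole gene set, is the unique limit of the principal
eigenvector as components are joined by vanishing bridges, and it
keeps the intended meaning -- stronger genes rank higher -- across
components.  (A power iteration from a uniform start would instead
converge to a projection whose per-component mass exactly cancels the
strength scale, ranking a strongly connected disease module no higher
than a weak background block.)
Per-network importances are z-scored over the active genes,
averaged across the networks being searched, and the top 10% of active
genes become seeds (`fraction = 0.10`; the search is not sensitive to
this fraction).

**Entropy objective.**  For a candidate module C, each member gene i
and network k contributes the binary entropy of
`p_ik = L_k(i) / (L_k(i) + Lbar_k(i))`, the fraction of i's total edge
weight that stays inside C; `H(C)` is the sum over members and
networks divided by |C|.  A sharply bounded module (all weight inside)
approaches 0, and each term is at most `log 2`.  Two conventions
matter and are deliberate:

* A gene with **no in-module connectivity** in network k (including no
  edges at all there) contributes `log 2`, the maximum.  The raw
  binary entropy is symmetric and would score p = 0 as zero -- as
  "coherent" as all-weight-inside -- so modules absent from one of the
  searched networks would rank as perfect, every condition-specific
  module would resurface at the top level, and permutation nulls would
  be saturated with zero-entropy artefacts.  The module definition this
  package implements is connectivity *stronger* than random in **all**
  searched networks, and the convention encodes exactly that.

**Greedy expansion.**  Each seed is expanded by entropy minimisation:
the candidate starts from the seed's closed neighbourhood (union over
the searched networks) and repeatedly applies the single best
strict-improvement move -- adding a gene adjacent to the module, or
dropping a non-seed member -- until no move decreases `H(C)`.  Ties
break by gene id, so the search is deterministic.  Starting from a
two-gene candidate cannot work with this objective: for any
clique-like module the member terms rise with every addition until
`p_ik` crosses 1/2, so a strict-descent greedy would stall immediately;
the neighbourhood start places the search on the downhill side of that
hump, and removals let it discard the neighbourhood's hangers-on.

**Refinement.**  Candidates smaller than 5 genes are dropped, and
overlapping candidates are merged (union, entropy recomputed) while
any pair has Jaccard index at least 0.5.

**Subsets and levels.**  The search runs independently on every
non-empty subset of the M networks (2^M − 1 searches; M ≤ 6 is
enforced).  Assigning each significant module to its level takes two
steps.  First, a *per-network presence test*: subset-level significance
alone cannot fix the level, because a module perfectly coherent in two
of three networks (H ≈ its two-network entropy + log 2) is still far
more coherent than degree-shuffled randomness judged over all three.
Each module is therefore tested in every network of its subset -- its
per-network entropy `H_k(C)/|C|` against 100 size-matched random gene
sets from that network's connected genes (the same empirical-null
pattern the dynamics score uses; the separation is wide, ~0.05 for a
genuinely present network versus ~log 2 for an absent one) -- and
demoted to the networks where it is present.  Second, a module kept
for subset S is discarded when a significant module of a strict
superset of S matches it at Jaccard ≥ 0.5 (and same-subset duplicates
keep the lowest-entropy copy); the survivors with |S| = m are the
m-level modules, so shared modules are never re-reported as
condition-specific ones and condition-specific modules are never
promoted to shared ones.

## Significance

Each network of a subset is shuffled by degree-preserving double-edge
swaps (10 attempted swaps per edge), with the multiset of edge weights
re-permuted over the rewired topology; the full search then re-runs on
the shuffled networks, and the scores of everything it finds are
pooled into the subset's null distribution (100 shuffles by default).
A module's empirical p-value is `(1 + #{null <= observed H}) /
(1 + #null)` -- the add-one form keeps p away from 0 with finite
permutations -- and p-values are Benjamini–Hochberg adjusted jointly
across all modules of all subsets (the conservative choice of family),
with significance called at adjusted p ≤ 0.05.

## Connectivity dynamics of shared modules

A shared module's induced weighted adjacency in each of its networks
is compared pairwise: the score is the mean over network pairs of
`||A_i - A_j||_2 / |C|`, with the induced 2-norm (largest singular
value) by default and the Frobenius norm behind `norm = "frobenius"`
("matrix L2 norm" admits both readings).  All unordered pairs are
averaged by default; `pairing = "adjacent"` averages consecutive pairs
in the supplied network order instead (the two coincide for two
networks).  The score is 0 exactly when the matrices are identical and
scales linearly with the weights; it counts both edge gains/losses and
weight changes.

The null for each module is the score of 100 random gene sets of the
same size drawn from the connected genes; the test is one-sided toward
large scores (more rewiring), BH-adjusted across the shared modules,
and a module is flagged *dynamic* at adjusted p ≤ 0.05 (pass
`alpha = 0.01` for the stricter call).

## Module statistics

* `mean_edge_weight()` -- differential activity of a module in one
  network; present edges only by default, because the weighting scheme
  assigns 0 to sub-threshold pairs and including them would conflate
  sparsity with inactivity (`dense = TRUE` divides by all pairs).
* `module_activity()` -- mean per-gene z-scored expression over
  members, per condition and time point.
* `regulation_call()` -- two-sided t-test of the member genes' mean
  expression differences against baseline at one time point (genes as
  the test unit by default; replicate-level pooling behind
  `unit = "replicate"`), calling up/down at p < 0.01.
* `phenotype_correlation()` -- Pearson correlation between activity and
  a phenotype measure across matched condition/time cells, restricted
  to the conditions the module was derived from; `fs_invert`
  implements the fractional-shortening convention (1 − FS, then
  per-measure z-scoring).
* `hypergeometric_enrichment()` -- upper-tail overlap tests against
  reference gene sets with BH control; collection-level specificity
  (modules with ≥ 1 enriched set) and sensitivity (sets with ≥ 1
  enriched module); `enrichment_fisher_test()` compares two such rates
  one-sidedly.
* `edge_delta_table()` -- the thresholded within-module weight changes
  behind rewiring displays.

## Synthetic data

`synthetic_truth()` / `simulate_panel()` generate the panels every test
runs on.  The model is single-factor Gaussian co-expression: module
genes share a latent factor per condition and sample (loading beta
gives pairwise correlation `beta^2 / (beta^2 + 1)`), plus a per-time
mean shift against baseline in noise-sd units; factors are
mean-centered within each condition so the realised differential
expression equals the specified effect.  Rewired modules split their
members across two sub-factors with a partition that changes from
condition to condition, so their edge pattern rewires while static
modules keep theirs.  The background is a set of large co-expression
blocks that switch on and off per condition -- real |r| ≥ 0.8
co-expression comes in large correlated blocks, and this is what keeps
the networks dense and connected (the regime the threshold-selection
rule presumes) and the permutation and random-gene-set nulls
non-degenerate.  A handful of strongly differential singleton "marker"
genes pin each network's `max |log p|` weight normaliser, which is
otherwise a bare extreme-value statistic whose jitter between
conditions masquerades as rewiring.  The phenotype is the summed
activity of the rewired modules plus noise, mimicking disease measures
driven by rewired biology.  DE p-values come from per-gene Welch
t-tests against baseline -- a stand-in any external table can replace.

Preset designs (`default_fixture()`): `tiny` (60 genes, 3 conditions ×
2 time × 3 replicates) for fast end-to-end runs; `small` (300 genes,
3 conditions × 4 × 4, three planted modules at levels 3/2/1) for
recovery benchmarks; `paper-shaped` (2000 genes, 3 conditions × 4 × 4);
`rewired-pair` (200 genes, 2 conditions × 4 × 16 replicates, four
rewired and two static shared modules) for the dynamics benchmark --
the deep replication there is what makes correlation estimates precise
enough that a static module's edge set is stable at the 0.8 threshold,
so the planted contrast is connectivity rewiring and nothing else.
What the generator does **not** emulate: count noise (values are
Gaussian on a log-like scale), gene-length and library-size artefacts,
overlapping modules, and correlated DE beyond the single-factor
structure.  Passing tests therefore demonstrate algorithmic
correctness and statistical behaviour under a controlled model, not
performance on any particular real dataset.

## Numerical choices

* All gene-order tie-breaks use byte-order (radix) sorting, so results
  do not depend on the session locale.
* Greedy moves must improve the entropy by more than 1e-12; near-ties
  resolve to the earlier gene in radix order.
* Conditioning sets in the partial screen are exact up to
  `conditioning_cap = 200` genes, then restricted to the genes most
  correlated with either endpoint; near-collinear conditioning genes
  (denominator below 1e-12) are skipped and counted.
* One run seed drives every stochastic stage through fixed per-stage
  offsets, so a configuration reproduces its module table byte for
  byte.

## Known limitations

* **Calibration on pure-noise networks is only approximate.**  Sample
  correlation matrices are positive semi-definite, so networks built
  from chance correlations are rich in triangles; degree-preserving
  edge shuffling destroys that transitivity, which makes observed
  noise networks look slightly more modular than their shuffles.  On
  pure-noise panels the empirical p-values are therefore mildly
  anti-conservative (a one-sided KS check against uniform at the 1%
  level fails for some simulation seeds).  On structured data this
  matters little -- planted modules sit far in the null's tail -- but
  borderline calls near the significance threshold deserve caution.
* The permutation null presumes networks whose shuffles stay
  connected.  On very sparse networks (mean degree near 1) shuffles
  fragment into small components that score as perfectly coherent
  modules, and significance degenerates; if most genes are
  disconnected at the chosen threshold, lower it.
* The min-over-z partial-correlation estimate is noisy below ~30
  samples per condition; with few samples the screen removes a
  substantial random fraction of genuine module edges (harmless for
  module discovery, but it blurs edge-level rewiring comparisons).
* Expansion is greedy; it can stop in a local entropy minimum, and the
  search makes no optimality claim beyond strict per-move improvement.

## Reproducing a run

```{r, eval = FALSE}
sim <- simulate_panel(default_fixture("small"), seed = 7)
dcns <- build_dcns(sim$panel, sim$de, delta = 0.8)
modules <- find_modules(dcns, n_rand = 100, seed = 123)
glance(modules)
dynamics <- mcds_significance(mcds_table(modules, dcns), dcns, seed = 5)
autoplot(modules)
```

The same chain, driven by a YAML configuration and a single seed, is
available from the shell as `mdmnet run --config cfg.yaml` (see
`exec/mdmnet`), and `scripts/acceptance.R` re-derives the package's
headline numbers from scratch.
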