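---
title: "Methods: matched-control inference of miRNA co-targeting networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: matched-control inference of miRNA co-targeting networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(CoTargetNet)
```

# The problem and the model

Predicted miRNA target sets are strongly confounded by 3'UTR properties:
long, GC-balanced, conserved UTRs carry predicted sites for many seed
families at once. Under a naive hypergeometric null (targets drawn
uniformly from the gene universe), essentially every pair of
broadly-targeting families would appear to "co-target". The model
implemented here replaces that null with a **matched-control null**: for a
family *B*, a control set C(B) is assembled so that its genes mirror the
targets' 3'UTR length, GC content and conservation, but are otherwise
exchangeable non-targets. If family *A*'s targets intersect T(B) no more
than they intersect C(B), the overlap is explained by UTR properties, not
by co-targeting.

For each unordered family pair (A, B), two directional 2×2 tables are
formed — `[[|T_A∩T_B|, |T_B|−·], [|T_A∩C_B|, |C_B|−·]]` and the
transposed roles — and each is tested with a one-sided exact
hypergeometric tail (`fisherGreater()`). Both directions must survive a
Benjamini–Hochberg adjustment at α for the pair to enter the network.

Assumptions worth keeping in mind:

* target sets are treated as flat gene sets; site counts, site types and
  context scores are not modelled;
* the control set conditions on three gene-level covariates only — any
  residual confounder (e.g. expression breadth of the host gene) is
  attributed to co-targeting;
* families are the units of testing; all member miRNAs of a family share
  its edges.

# Key parameters

| parameter | default | rationale |
|---|---|---|
| `min_targets` | 300 | families with small predicted target sets give unstable overlap statistics; 300 conserved targets is the conventional inclusion bar for broadly conserved families |
| `utr_window` | 0.85–1.15 (multiplicative) | tight enough that length distributions match, loose enough that most targets find a control |
| `gc_window` | 0.95–1.05 | GC varies little across genes; a ±5% ratio window keeps the distributions aligned |
| `phylop_window` | 0.8–1.2 | conservation scores are noisier per gene; a ±20% window balances pool size against similarity |
| `max_mismatch` | 1 | families whose 7-nt seeds are identical up to one substitution share targets trivially through the seed itself and are excluded a priori |
| `alpha` | 0.05 | applied to both adjusted directional p-values (the bidirectional rule is therefore conservative) |
| DE thresholds | padj < 0.05, abs(log2FC) > 0.5 | strict inequalities; a fold change of exactly 0.5 is not called |
| CPM filter | > 10 CPM in ≥ 5 samples | expression floor for counting a miRNA as detected |

Multiplicative windows are orientation-normalized
(`lo = min(w1·t, w2·t)`, `hi = max(...)`, endpoints inclusive) so that
targets with negative phyloP values still define a proper interval.

# Design decisions

Several choices were genuinely open; the package fixes them as follows,
each switchable where a sensitivity analysis is plausible.

* **Seed window.** Seeds are modelled as 7-mers over {A, U, C, G}
  representing mature-miRNA positions 2–8. Seed-similarity exclusion uses
  the Hamming distance at aligned positions; shifted/offset seed matches
  are not considered.
* **Sidedness.** The pair test is one-sided for enrichment, because the
  scientific claim is an odds ratio above 1 (shared targets in excess of
  the matched null); depletion is not of interest at the pair level. The
  intra- vs inter-modular module test (`intraInterTest()`) is two-sided,
  since either direction of association is interpretable there.
* **BH family.** All 2·P directional p-values from the P tested pairs are
  adjusted together (`bh_pooling = "pooled"`); per-direction pooling is
  available. Pooling is the stricter, simpler choice and makes the two
  directions exchangeable.
* **Control pool.** Candidates are drawn from genes outside the family's
  own target set (`all_non_targets`): controls represent non-target
  background, and allowing self-targets would deflate the null. A control
  may, however, be a target of the *partner* family — forbidding that
  would force expected overlaps to zero and break the test. Controls are
  sampled without replacement within a family (duplicated controls would
  distort intersection counts); a single surviving candidate is used as
  is. Targets are visited in lexicographic gene-id order so a fixed seed
  reproduces the control set exactly.
* **Reported odds ratio.** Each pair carries two directional ORs
  (Haldane–Anscombe 0.5 correction only when a zero cell occurs, and only
  for the OR — never for the exact test); the ranking OR is their
  geometric mean.
* **Expression correlate.** Degree–expression correlation uses per-miRNA
  mean CPM across all samples, log2 with pseudocount 1, with the family
  degree broadcast to member miRNAs.
* **Trait encoding.** Developmental stages are coded as equally spaced
  integers in their given order (E14 = 1, E17 = 2, P0 = 3) for all trait
  correlations.
* **Eigengenes.** Computed on per-miRNA z-scored rows (the standard
  co-expression convention), as the first right-singular vector (unit
  norm), sign-oriented to correlate non-negatively with the module's mean
  standardized profile. Constant rows are rejected by name rather than
  silently dropped.
* **Module analysis unit.** x and y in M = x(x−1)/2 and N = xy count
  miRNA *families* present in the network — the units actually tested —
  with `unit = "mirna"` available to count individual miRNAs instead. The
  module test is computed per module; pooling two modules is a caller-side
  relabeling (the test is invariant to how the "other" modules are split).
* **Percentages.** Overlap summaries round half-up to integers. One
  published phrasing of such a summary corresponds to 72/110 = 65.45%,
  printed as 66%; half-up rounding gives 65%, and the discrepancy is left
  visible rather than special-cased.
* **Generalized exact test.** The 2×3 DE-enrichment test enumerates all
  tables with the observed margins when the total is ≤ 500 (the table
  count grows combinatorially beyond that) and otherwise estimates the
  same tail by Monte-Carlo over `r2dtable()` draws with a fixed seed and a
  reported replicate count; a collapsed 2×2 view is available through the
  per-column odds ratios.

# The synthetic-study generator

`generateStudy()` emulates the statistical structure the analysis assumes,
so that every stage can be validated against known ground truth:

* **Gene features**: 3'UTR lengths lognormal(meanlog 7, sdlog 0.6)
  (median ≈ 1.1 kb), GC beta(40, 45), phyloP normal(1, 0.3). No public
  empirical fit stands behind these defaults; they are chosen once as
  plausible for a mammalian 3'UTR annotation and are configuration
  parameters, not constants.
* **Catalog**: 40 families of 1–3 members with distinct 7-mer seeds kept
  at pairwise Hamming distance ≥ 2, so only deliberately planted
  near-identical pairs trigger the exclusion rule.
* **Target sets**: 300–400 targets per family over 5000 genes, sampled
  without replacement with inclusion probability ∝ `utr_length^utr_bias`
  (default bias 1), reproducing the empirical association between UTR
  length and the number of targeting families. With `utr_bias = 0` the
  overlap of two families is exactly hypergeometric, which is how the
  generator's null is verified by goodness of fit.
* **Planted pairs**: for a planted pair (A, B) the shared-target count s
  is binomial with mean κ·|A|·|B|/G, and the two remainders are drawn
  from disjoint pools so the realised overlap equals s exactly. Filling
  the remainders independently instead would add an incidental overlap
  inflated by the UTR-weight dispersion (a factor ≈ 1 + CV², about 1.4 at
  the default sdlog), making κ miscalibrated; the disjoint-pool scheme
  keeps both the marginal set sizes and the planted expectation exact.
* **Counts**: negative binomial (size 10; `Inf` gives exact Poisson)
  around lognormal per-miRNA baselines × module stage profiles ×
  library size/10⁶, with library sizes lognormal around 2×10⁷ reads so
  CPM filtering operates at a realistic scale. Twelve samples — three
  stages × four replicates, alternating sex labels — match a small bulk
  developmental design. Modules cycle through decreasing, increasing,
  peaked and flat stage profiles (geometric factors 4:2:1), emulating
  early-peaking and late-rising co-expression modules.

What the generator does **not** emulate: read-level noise and mapping
artefacts, isomiRs, genome coordinates, correlated gene features (UTR
length, GC and conservation are drawn independently), miRNA-level
deviations from the family target set, and unassigned/grey module
membership. Green tests therefore certify the statistical machinery and
its calibration under the stated generative model — not the biological
accuracy of any particular target database.

# Numerical choices and degenerate inputs

* `fisherGreater()` sums the hypergeometric PMF over the upper support via
  `lchoose`, clamped at 1; validated exhaustively against an independent
  factorial-form enumeration for every 2×2 table with total ≤ 40
  (max |Δp| < 1e−10) and spot-checked against `stats::fisher.test`.
* Ties in `topPairs()` break lexicographically by family ids, making
  reports byte-stable across runs.
* Per-family RNG substreams are derived by hashing the family id into a
  31-bit offset, so control matching is reproducible regardless of
  processing order; all generator outputs are pure functions of
  (config, seed).
* Degenerate inputs fail loudly and by name: constant expression rows,
  constant traits, empty target sets, zero library sizes, targets without
  features, families without control sets.
* Wilcoxon similarity checks use the normal approximation
  (`exact = FALSE`), appropriate at the hundreds-of-pairs scale where the
  check is meaningful; at least 8 matched pairs are required.

# Validation problem sizes

The test suite and the acceptance script validate the pipeline at desk
scale, chosen so each property is measured with useful power while a full
run stays in the minutes range: null calibration over 20 unplanted studies
(40 families × ~350 targets × 5000 genes; the bidirectional call rate
never exceeded α), planted-pair recovery over 5 studies with 10 pairs at
κ = 3 (~780 tested pairs each; mean sensitivity ≥ 0.9, precision ≥ 0.8),
matching quality over 20 seeds at 400 targets (100% window compliance;
all three Wilcoxon p > 0.05 in ≥ 90% of seeds), overlap calibration over
≥ 100 generator seeds, and eigengene recovery from 12-sample NB counts
(|cor| with the planted profile ≥ 0.95).

# Known limitations

* The matched-control null conditions on three covariates; systematic
  biases outside them (annotation depth, paralogy, expression breadth)
  propagate into the network.
* Greedy without-replacement matching can strand a small number of
  targets even when a perfect bipartite matching exists; the package
  deliberately keeps the simple greedy scheme (absent controls shrink
  |C| and the test accounts for that) rather than solving an assignment
  problem.
* Only pairwise co-targeting is tested; higher-order (triple+) sharing is
  out of scope.
* Module detection itself (co-expression network construction, tree
  cutting) is consumed as input, never computed here; eigengene-based
  statistics inherit whatever instability the upstream clustering has.
* Control sets depend on the RNG; at default pool richness this moves
  directional p-values only marginally, but edge cases near α can flip —
  provenance (seed, config hash) is recorded in every output for exact
  reproduction.
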