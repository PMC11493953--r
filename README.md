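# CoTargetNet

Inference of **miRNA co-targeting networks**: which pairs of miRNA seed
families share significantly more target genes than expected by chance?

Individual miRNAs repress transcripts by binding sites in 3'UTRs, and
miRNAs expressed in the same tissue often regulate overlapping gene sets —
either cooperatively (co-expressed miRNAs reinforcing repression) or
antagonistically across developmental stages. Deciding whether an observed
target overlap is *surprising* is not trivial, because long, conserved
3'UTRs accumulate predicted sites for many miRNAs: a naive background makes
every pair of broadly targeting families look associated. CoTargetNet
implements a matched-control framework that removes this bias, together
with the module-level and expression-level statistics used to characterise
the resulting network in developing-brain studies. All inputs are plain
tab-separated tables (TargetScan-style target catalogs, per-gene 3'UTR
features, count matrices, module assignments, DE result tables), and a
synthetic-study generator with planted ground truth makes the whole chain
testable end to end.

## The statistic

For each miRNA family *F* (miRNAs sharing a 7-nt seed, hence identical
predicted target sets, with ≥ 300 targets after filtering), a **matched
control gene set** C(F) is built by case-control selection: each target
gene is paired with a random non-target gene whose

- 3'UTR length lies within 0.85–1.15×,
- GC content within 0.95–1.05×, and
- phyloP conservation score within 0.8–1.2×

of the target's values (Wilcoxon rank-sum tests verify that target and
control feature distributions are indistinguishable). For every candidate
pair of families (A, B) whose seeds differ by more than one mismatch, two
directional 2×2 tables are tested with one-sided Fisher's exact tests:

```
            in T_B          not            |            in C_B        not
  in T_A      a         |T_B| − a          |  in T_A      c        |C_B| − c
```

i.e. the observed shared-target count *a* = |T_A ∩ T_B| is compared with
the matched-control intersection *c* = |T_A ∩ C_B|, and vice versa. All
directional p-values are adjusted in one Benjamini–Hochberg family, and
(A, B) is called a **bidirectional co-targeting pair** only if *both*
adjusted p-values fall below α = 0.05. Effect sizes are odds ratios
(Haldane-corrected at zero cells); pairs are ranked by the geometric mean
of the two directional ORs.

Around the core test the package provides: network summaries (degree
distributions, degree–expression correlation, per-gene pair counts vs
3'UTR length, strongest pairs); co-expression module statistics
(eigengene = first PC of the z-scored module expression matrix,
module–trait correlation, module membership, trait significance, and the
intra- vs inter-modular association test on the table
[[m, M−m], [n, N−n]] with M = x(x−1)/2 and N = xy); and expression
utilities (CPM, low-expression filtering, DE classification at
|log2FC| > 0.5 and adjusted p < 0.05, a generalized exact test for
DE-class enrichment in target sets, overlap summaries, z-score/min-max
normalization, ΔΔCT relative quantification).

## Worked example

```r
library(CoTargetNet)

cfg     <- simConfig(n_planted_pairs = 10, overlap_multiplier = 3, rng_seed = 42)
bundle  <- generateStudy(cfg)                       # 40 families, 5000 genes, 12 samples
families <- filterFamilies(catalog(bundle), min_targets = 300)
controls <- buildControlSets(families, matchingConfig(rng_seed = 42))
validateMatching(controls[[1]], geneFeatures(families))
#>      feature   p_value flagged
#> 1 utr_length 0.6422623   FALSE
#> 2         gc 0.9875356   FALSE
#> 3     phylop 0.8534546   FALSE

network <- detectPairs(families, controls, excludedPairs(families), alpha = 0.05)
network
#> CoTargetNetwork: 40 families, 780 tested pairs, 10 significant (alpha = 0.05)
#>   mean family degree: 0.5

topPairs(network, 3)[, c("family_a", "family_b", "n_shared", "or_combined")]
#>   family_a family_b n_shared or_combined
#> 1   fam029   fam039       68    3.391022
#> 2   fam008   fam022       67    3.330365
#> 3   fam014   fam018       70    3.241297
```

The matching report shows the control genes are distributionally
indistinguishable from the targets (all p ≫ 0.05). Of 780 tested family
pairs the bidirectional rule keeps exactly the 10 planted ones: each shares
~70 targets where independence predicts ~25, giving combined odds ratios
around 3. `plantedPairs(bundle)` confirms the recovered pairs are the
planted ground truth.

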