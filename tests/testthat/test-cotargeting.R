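test_that("fisherGreater reproduces hand-derived exact tail probabilities", {
  # overlap at the minimum of its support: the whole distribution
  expect_equal(fisherGreater(rbind(c(0, 10), c(5, 5))), 1)
  # worked example: p = 2730/38760 = 13013/184756
  expect_equal(fisherGreater(rbind(c(5, 5), c(1, 9))), 2730 / 38760,
               tolerance = 1e-12)
  # single most-extreme table
  expect_equal(fisherGreater(rbind(c(10, 0), c(0, 10))), 1 / choose(20, 10),
               tolerance = 1e-12)
  expect_error(fisherGreater(c(-1, 2, 3, 4)), "non-negative")
  expect_error(fisherGreater(c(1, 2, 3)), "2x2")
})

test_that("fisherGreater agrees with stats::fisher.test on random tables", {
  set.seed(42)
  for (i in 1:200) {
    tab <- matrix(rpois(4, 6), 2)
    expect_equal(fisherGreater(tab),
                 fisher.test(tab, alternative = "greater")$p.value,
                 tolerance = 1e-9)
  }
})

test_that("one-sided p never increases when the overlap grows", {
  # fixed margins: move one unit from b to a and from d to c keeps margins
  # of the success column growing; instead fix N, K, n and vary a directly
  for (seed in 1:20) {
    set.seed(seed)
    n <- sample(5:15, 1); K <- sample(5:15, 1); N <- n + K + sample(0:10, 1)
    amax <- min(K, n); amin <- max(0, n + K - N)
    p <- vapply(amin:amax, function(a)
      fisherGreater(c(a, n - a, K - a, N - K - n + a)), numeric(1))
    expect_true(all(diff(p) <= 1e-12))
  }
})

test_that("oddsRatio follows the corrected cross-product formula", {
  expect_equal(oddsRatio(rbind(c(2, 3), c(1, 4))), 8 / 3)
  expect_equal(oddsRatio(rbind(c(2, 0), c(1, 4))), 15.0)
  for (k in c(1, 3, 10)) {
    expect_equal(oddsRatio(matrix(k, 2, 2)), 1)
  }
})

test_that("bhAdjust performs the step-up adjustment", {
  expect_equal(bhAdjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bhAdjust(0.2), 0.2)
  expect_equal(bhAdjust(rep(1, 5)), rep(1, 5))
  expect_error(bhAdjust(c(0.5, 1.2)), "0, 1")
  expect_error(bhAdjust(c(0.5, NA)), "0, 1")
})

test_that("disjoint target sets yield no co-targeting edge", {
  feat <- makeFeatures(400, seed = 7)
  cat1 <- makeCatalog(list(f1 = feat$gene_id[1:50],
                           f2 = feat$gene_id[51:100]),
                      features = feat)
  cs <- buildControlSets(cat1, matchingConfig(rng_seed = 7))
  net <- detectPairs(cat1, cs, NULL)
  expect_equal(nrow(networkEdges(net)), 1)
  expect_false(any(networkEdges(net)$significant))
  expect_equal(networkEdges(net)$n_shared, 0)
})

test_that("identical target sets are detected as a co-targeting pair", {
  feat <- makeFeatures(5000, seed = 8)
  shared <- sample(feat$gene_id, 400)
  cat1 <- makeCatalog(list(f1 = shared, f2 = shared), features = feat)
  cs <- buildControlSets(cat1, matchingConfig(rng_seed = 8))
  net <- detectPairs(cat1, cs, NULL, alpha = 0.05)
  e <- networkEdges(net)
  expect_true(e$significant)
  expect_equal(e$n_shared, 400L)
  expect_gt(e$or_combined, 1)
})

test_that("detection is invariant to family labels and symmetric in direction", {
  b <- generateStudy(simConfig(n_genes = 1500, n_families = 6,
                               targets_per_family = 120, n_planted_pairs = 2,
                               rng_seed = 31))
  cat1 <- catalog(b)
  cfg <- matchingConfig(rng_seed = 31)
  cs <- buildControlSets(cat1, cfg)
  net1 <- detectPairs(cat1, cs, NULL)
  # swap the ids of two families everywhere (targets, mirnas, controls)
  swap <- function(x) {
    x[x == "fam001"] <- "zzz"
    x[x == "fam002"] <- "fam001"
    x[x == "zzz"] <- "fam002"
    x
  }
  cat2 <- cat1
  names(cat2@targets) <- swap(names(cat2@targets))
  names(cat2@target_conserved) <- swap(names(cat2@target_conserved))
  cat2@mirnas$family_id <- swap(cat2@mirnas$family_id)
  cs2 <- cs
  names(cs2) <- swap(names(cs2))
  for (f in names(cs2)) cs2[[f]]@family_id <- f
  net2 <- detectPairs(cat2, cs2, NULL)
  key <- function(fa, fb) sort(paste(pmin(fa, fb), pmax(fa, fb)))
  s1 <- significantEdges(net1)
  s2 <- significantEdges(net2)
  # swap is an involution: mapping net2's labels back must recover net1
  expect_identical(key(s1$family_a, s1$family_b),
                   key(swap(s2$family_a), swap(s2$family_b)))
  # the unordered pair of directional p-values is invariant under the
  # relabeling (directions follow the labels)
  dirPairs <- function(net) {
    e <- networkEdges(net)
    sort(paste(round(pmin(e$p_ab, e$p_ba), 10),
               round(pmax(e$p_ab, e$p_ba), 10)))
  }
  expect_identical(dirPairs(net1), dirPairs(net2))
})

test_that("excluded pairs are never tested", {
  feat <- makeFeatures(500, seed = 9)
  cat1 <- makeCatalog(list(f1 = feat$gene_id[1:60], f2 = feat$gene_id[31:90],
                           f3 = feat$gene_id[61:120]), features = feat)
  cs <- buildControlSets(cat1, matchingConfig(rng_seed = 9))
  excl <- data.frame(family_a = "f1", family_b = "f2")
  net <- detectPairs(cat1, cs, excl)
  e <- networkEdges(net)
  expect_equal(nrow(e), 2)
  expect_false(any(e$family_a == "f1" & e$family_b == "f2"))
  expect_error(detectPairs(cat1, cs[-1], NULL), "without control set")
})

test_that("degrees satisfy the handshake identity over miRNAs", {
  fams <- sprintf("f%d", 1:4)
  edges <- data.frame(family_a = c("f1", "f1", "f2"),
                      family_b = c("f2", "f3", "f3"),
                      significant = TRUE, stringsAsFactors = FALSE)
  net <- makeNetwork(edges, fams, n_members = c(2L, 1L, 3L, 1L))
  dd <- degreeDistribution(net)
  # triangle f1-f2-f3: family degrees 2,2,2; f4 isolated
  expect_equal(unname(dd$degrees[c("f1-m1", "f2-m1", "f3-m2", "f4-m1")]),
               c(2L, 2L, 2L, 0L))
  sig <- significantEdges(net)
  members <- setNames(networkNodes(net)$n_members, networkNodes(net)$family_id)
  expect_equal(sum(dd$degrees),
               sum(members[sig$family_a] + members[sig$family_b]))
  # empty network: all degrees zero
  net0 <- makeNetwork(edges[0, ], fams)
  expect_true(all(degreeDistribution(net0)$degrees == 0))
})

test_that("degree-expression correlation behaves at its edge cases", {
  fams <- sprintf("f%d", 1:4)
  edges <- data.frame(family_a = c("f1", "f1", "f1", "f2"),
                      family_b = c("f2", "f3", "f4", "f3"),
                      significant = TRUE, stringsAsFactors = FALSE)
  net <- makeNetwork(edges, fams)
  deg <- degreeDistribution(net)$degrees  # 3, 2, 2, 1
  expr <- setNames(2^deg - 1, names(deg))  # log2(expr + 1) == degree
  res <- degreeExpressionCorrelation(net, expr)
  expect_equal(res$r, 1, tolerance = 1e-12)
  # all degrees equal -> undefined correlation
  tri <- makeNetwork(data.frame(family_a = c("f1", "f1", "f2"),
                                family_b = c("f2", "f3", "f3"),
                                significant = TRUE),
                     sprintf("f%d", 1:3))
  expect_error(degreeExpressionCorrelation(tri, setNames(c(1, 5, 9),
                                                         paste0("f", 1:3, "-m1"))),
               "zero variance")
  expect_error(degreeExpressionCorrelation(net, expr[1:2]), "at least 3")
})

test_that("gene pair counts double-count shared genes consistently", {
  feat <- makeFeatures(300, seed = 10)
  cat1 <- makeCatalog(list(f1 = feat$gene_id[1:80], f2 = feat$gene_id[41:120],
                           f3 = feat$gene_id[81:160]), features = feat)
  edges <- data.frame(family_a = c("f1", "f2"), family_b = c("f2", "f3"),
                      significant = TRUE, stringsAsFactors = FALSE)
  net <- makeNetwork(edges, c("f1", "f2", "f3"))
  gpc <- genePairCounts(net, cat1)
  counts <- setNames(gpc$counts$n_pairs, gpc$counts$gene_id)
  # genes shared by exactly one significant pair have count 1:
  # f1&f2 share 41:80, f2&f3 share 81:120
  expect_true(all(counts[feat$gene_id[41:80]] == 1))
  expect_true(all(counts[feat$gene_id[81:120]] == 1))
  # genes outside every shared set have count 0
  expect_equal(unname(counts[feat$gene_id[1]]), 0L)
  expect_true(all(counts[feat$gene_id[121:160]] == 0))
  # conservation: total count equals the summed shared-set sizes
  expect_equal(sum(counts), 40L + 40L)
})

test_that("topPairs ranks by combined OR with stable lexicographic ties", {
  edges <- data.frame(family_a = c("f1", "f1", "f2"),
                      family_b = c("f2", "f3", "f3"),
                      or_ab = c(15, 3, 3), or_ba = c(15, 3, 3),
                      significant = TRUE, stringsAsFactors = FALSE)
  net <- makeNetwork(edges, sprintf("f%d", 1:3))
  top <- topPairs(net, k = 10)  # k beyond the edge count returns all
  expect_equal(nrow(top), 3)
  expect_equal(top$or_combined[1], 15)
  # tie between (f1,f3) and (f2,f3): lexicographic on family_a
  expect_equal(top$family_a[2:3], c("f1", "f2"))
  expect_identical(topPairs(net, 10), topPairs(net, 10))
  expect_equal(nrow(topPairs(net, 1)), 1)
  expect_error(topPairs(net, 0), "k")
})
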