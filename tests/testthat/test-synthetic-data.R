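test_that("simConfig rejects degenerate or infeasible configurations", {
  expect_error(simConfig(n_genes = 0), "n_genes")
  expect_error(simConfig(n_families = 0), "n_families")
  expect_error(simConfig(nb_dispersion = 0), "nb_dispersion")
  expect_error(simConfig(nb_dispersion = -1), "nb_dispersion")
  expect_error(simConfig(targets_per_family = 6000, n_genes = 5000),
               "exceeds n_genes")
  expect_error(simConfig(n_families = 4^7 + 1), "seeds")
  expect_error(simConfig(utr_sdlog = 0), "positive")
  # expected planted overlap must stay below min(|A|, |B|)
  expect_error(simConfig(n_genes = 500, targets_per_family = c(100, 400),
                         n_planted_pairs = 1, overlap_multiplier = 3),
               "planted overlap")
})

test_that("generation is a pure function of (config, seed)", {
  cfg <- simConfig(n_genes = 300, n_families = 6,
                   targets_per_family = c(20, 40), n_planted_pairs = 2,
                   rng_seed = 11)
  b1 <- generateStudy(cfg)
  b2 <- generateStudy(cfg)
  expect_identical(SummarizedExperiment::assay(b1),
                   SummarizedExperiment::assay(b2))
  expect_identical(targetSets(catalog(b1)), targetSets(catalog(b2)))
  expect_identical(geneFeatures(catalog(b1)), geneFeatures(catalog(b2)))
  expect_identical(plantedPairs(b1), plantedPairs(b2))
  b3 <- generateStudy(cfg, seed = 12)
  expect_false(identical(SummarizedExperiment::assay(b1),
                         SummarizedExperiment::assay(b3)))
})

test_that("gene features follow the configured distributions", {
  cfg <- simConfig(n_genes = 10000, rng_seed = 3)
  feat <- generateGeneFeatures(cfg)
  expect_equal(nrow(feat), 10000)
  expect_true(all(feat$utr_length > 0))
  expect_true(all(feat$gc > 0 & feat$gc < 1))
  # lognormal(meanlog = 7) has median e^7
  expect_lt(abs(median(feat$utr_length) - exp(7)) / exp(7), 0.10)
})

test_that("catalog has distinct family seeds and the requested shape", {
  cfg <- simConfig(n_families = 1, members_per_family = 3, rng_seed = 5)
  cat1 <- generateCatalog(cfg)
  expect_equal(nrow(cat1), 3)
  expect_equal(length(unique(cat1$seed)), 1)

  # one value per family: 77 families whose member counts sum to 106
  members <- c(rep(2L, 29), rep(1L, 48))
  cfg2 <- simConfig(n_families = 77, members_per_family = members,
                    rng_seed = 5)
  cat2 <- generateCatalog(cfg2)
  expect_equal(length(unique(cat2$family_id)), 77)
  expect_equal(nrow(cat2), 106)
  # partition: each miRNA in exactly one family, members share the seed
  expect_false(anyDuplicated(cat2$mirna_id) > 0)
  expect_true(all(tapply(cat2$seed, cat2$family_id,
                         function(s) length(unique(s))) == 1))
  # family seeds pairwise distinct
  fam_seed <- unique(cat2[, c("family_id", "seed")])
  expect_false(anyDuplicated(fam_seed$seed) > 0)
})

test_that("near-identical seed planting creates exactly one distance-1 pair", {
  cfg <- simConfig(n_families = 8, plant_near_identical_seeds = 1,
                   rng_seed = 9)
  cat1 <- generateCatalog(cfg)
  fam_seed <- unique(cat1[, c("family_id", "seed")])
  d <- outer(fam_seed$seed, fam_seed$seed,
             Vectorize(function(x, y) seedHamming(x, y)))
  close_pairs <- sum(d[upper.tri(d)] <= 1)
  expect_equal(close_pairs, 1)
})

test_that("unplanted target sets match independence expectations", {
  # E[|A intersect B|] = |A||B|/G for uniform independent draws
  cfg <- simConfig(n_genes = 6000, n_families = 2,
                   targets_per_family = c(300, 400), utr_bias = 0,
                   rng_seed = 1)
  cfg$targets_per_family <- c(300L, 400L)  # per-family sizes
  overlaps <- vapply(seq_len(200), function(s) {
    feat <- generateGeneFeatures(cfg, seed = s)
    cat1 <- generateCatalog(cfg, seed = s)
    ts <- generateTargetSets(cfg, feat, cat1, seed = s)
    length(intersect(ts$targets[[1]], ts$targets[[2]]))
  }, numeric(1))
  expect_lt(abs(mean(overlaps) - 300 * 400 / 6000), 3)
})

test_that("planted overlap is calibrated to kappa * |A||B| / G", {
  cfg <- simConfig(n_genes = 2000, n_families = 2, targets_per_family = 150,
                   n_planted_pairs = 1, overlap_multiplier = 2, rng_seed = 1)
  expected <- 2 * 150 * 150 / 2000
  overlaps <- vapply(seq_len(120), function(s) {
    feat <- generateGeneFeatures(cfg, seed = s)
    cat1 <- generateCatalog(cfg, seed = s)
    ts <- generateTargetSets(cfg, feat, cat1, seed = s)
    ov <- length(intersect(ts$targets[[ts$truth$family_a]],
                           ts$targets[[ts$truth$family_b]]))
    expect_identical(ov, length(intersect(ts$targets[[1]],
                                          ts$targets[[2]])))
    expect_equal(ov, ts$truth$n_shared)
    ov
  }, numeric(1))
  expect_lt(abs(mean(overlaps) - expected) / expected, 0.10)
  # kappa = 1 with no planting leaves the truth list empty
  ts0 <- generateTargetSets(simConfig(n_genes = 500, n_families = 3,
                                      targets_per_family = 50,
                                      overlap_multiplier = 1, rng_seed = 2),
                            makeFeatures(500),
                            generateCatalog(simConfig(n_genes = 500,
                                                      n_families = 3,
                                                      targets_per_family = 50,
                                                      rng_seed = 2)))
  expect_equal(nrow(ts0$truth), 0)
})

test_that("UTR-length bias makes long-UTR genes accumulate targeting families", {
  cfg <- simConfig(n_genes = 5000, n_families = 40,
                   targets_per_family = c(300, 400), rng_seed = 21)
  feat <- generateGeneFeatures(cfg)
  cat1 <- generateCatalog(cfg)
  ts <- generateTargetSets(cfg, feat, cat1)
  hits <- table(factor(unlist(ts$targets, use.names = FALSE),
                       levels = feat$gene_id))
  rho <- cor(feat$utr_length, as.numeric(hits), method = "spearman")
  expect_gt(rho, 0)
})

test_that("non-planted pairwise overlap follows the hypergeometric null", {
  # without the UTR-length bias the overlap of two independent uniform
  # draws is exactly hypergeometric; chi-square goodness of fit over
  # 1000 replicates
  G <- 200; nA <- 30; nB <- 40
  cfg <- simConfig(n_genes = G, n_families = 2, targets_per_family = c(nA, nB),
                   utr_bias = 0, rng_seed = 1)
  cfg$targets_per_family <- c(nA, nB)
  ov <- vapply(seq_len(1000), function(s) {
    feat <- generateGeneFeatures(cfg, seed = 5000 + s)
    cat1 <- generateCatalog(cfg, seed = 5000 + s)
    ts <- generateTargetSets(cfg, feat, cat1, seed = 5000 + s)
    length(intersect(ts$targets[[1]], ts$targets[[2]]))
  }, numeric(1))
  support <- 0:min(nA, nB)
  probs <- dhyper(support, nA, G - nA, nB)
  # merge low-expectation bins into the tails
  keep <- which(probs * 1000 >= 5)
  lo <- min(keep); hi <- max(keep)
  bins <- c(sum(ov <= support[lo]),
            vapply(support[(lo + 1):(hi - 1)],
                   function(k) sum(ov == k), numeric(1)),
            sum(ov >= support[hi]))
  pbin <- c(sum(probs[1:lo]), probs[(lo + 1):(hi - 1)],
            sum(probs[hi:length(probs)]))
  stat <- sum((bins - 1000 * pbin)^2 / (1000 * pbin))
  p <- pchisq(stat, df = length(bins) - 1, lower.tail = FALSE)
  expect_gt(p, 0.01)
})

test_that("counts approach the Poisson limit at infinite dispersion", {
  cfg <- simConfig(n_families = 1, targets_per_family = 10, n_genes = 100,
                   stages = "E14", replicates_per_stage = 2,
                   nb_dispersion = Inf, baseline_meanlog = log(100),
                   baseline_sdlog = 0, lib_size_meanlog = log(1e6),
                   lib_size_sdlog = 0, n_modules = 1, rng_seed = 8)
  # 5000 miRNAs sharing one flat module: every NB mean is exactly 100
  cat1 <- data.frame(mirna_id = sprintf("m%04d", 1:5000),
                     family_id = "fam001", seed = "AAAAAAA",
                     conserved = TRUE, stringsAsFactors = FALSE)
  mods <- list(assignments = setNames(rep("black", 5000), cat1$mirna_id),
               profiles = matrix(1, 1, 1,
                                 dimnames = list("black", "E14")))
  cnt <- generateCounts(cfg, cat1, mods$assignments, mods$profiles)
  draws <- as.numeric(cnt$counts)
  expect_equal(length(draws), 10000)
  expect_lt(abs(mean(draws) - 100) / 100, 0.05)
  expect_lt(abs(var(draws) - mean(draws)) / mean(draws), 0.10)
})

test_that("flat module profiles produce no stage effect", {
  cfg <- simConfig(n_genes = 200, n_families = 10, targets_per_family = 20,
                   n_modules = 1, rng_seed = 13)
  cat1 <- generateCatalog(cfg)
  mods <- assignModules(cfg, cat1)
  mods$profiles[] <- 1
  cnt <- generateCounts(cfg, cat1, mods$assignments, mods$profiles)
  logcpm <- log2(cpm(cnt$counts) + 1)
  fit <- stats::aov(colMeans(logcpm) ~ cnt$metadata$stage)
  p <- summary(fit)[[1]][["Pr(>F)"]][1]
  expect_gt(p, 0.01)
})

test_that("StudyBundle validity ties counts, catalog, modules and features", {
  b <- generateStudy(simConfig(n_genes = 300, n_families = 5,
                               targets_per_family = 30, rng_seed = 4))
  expect_true(validObject(b))
  expect_true(all(rownames(b) %in% mirnaInfo(catalog(b))$mirna_id))
  expect_true(all(rownames(b) %in% names(moduleAssignments(b))))
  tg <- unique(unlist(targetSets(catalog(b)), use.names = FALSE))
  expect_true(all(tg %in% geneFeatures(catalog(b))$gene_id))
})
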