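## Synthetic study generator: emulates the statistical structure the
## co-targeting analysis assumes (seed families, UTR-length-biased target
## catalogs with planted co-targeting pairs, stage-structured NB counts)
## so every downstream stage can be tested end to end.

.MODULE_COLORS <- c("black", "green", "turquoise", "blue", "brown", "yellow",
                    "red", "pink", "magenta", "purple")

# deterministic 31-bit polynomial hash, used to derive per-entity RNG
# substreams so parallel order cannot change results
.hashString <- function(x) {
  h <- 0
  for (k in utf8ToInt(x)) h <- (h * 31 + k) %% 2147483647
  as.integer(h)
}

.subSeed <- function(base, offset, id = NULL) {
  h <- if (is.null(id)) 0L else .hashString(id)
  as.integer((as.numeric(base) * 7919 + offset * 104729 + h) %% 2147483647)
}

# scalar -> constant, length-n -> per-entity sizes, length-2 -> uniform range
.drawSizes <- function(spec, n) {
  if (length(spec) == n && n != 1L) return(as.integer(spec))
  if (length(spec) == 1L) return(rep(as.integer(spec), n))
  if (length(spec) == 2L)
    return(sample(seq(as.integer(spec[1]), as.integer(spec[2])), n,
                  replace = TRUE))
  stop("size specification must be a scalar, a (lo, hi) range, or one value per entity",
       call. = FALSE)
}

.cfgStop <- function(...) stop("invalid SimConfig: ", sprintf(...), call. = FALSE)

#' Configuration of a synthetic co-targeting study
#'
#' Defines the study conditions a generated [StudyBundle-class] emulates:
#' catalog shape (families, members, target-set sizes), per-gene 3'UTR
#' features, planted co-targeting pairs, stage-structured co-expression
#' modules and the negative-binomial count model.
#'
#' Defaults mirror a desk-scale version of a bulk small-RNA developmental
#' study: three ordered stages (E14, E17, P0) with four replicates each
#' (two per sex, 12 samples), 40 seed families of 300-400 targets over
#' 5000 genes, lognormal 3'UTR lengths (median about 1.1 kb), and library
#' sizes around 2e7 reads so CPM filtering operates at a realistic scale.
#'
#' @param n_genes number of annotated genes.
#' @param n_families number of miRNA seed families.
#' @param members_per_family scalar or (lo, hi) range of miRNAs per family.
#' @param targets_per_family scalar or (lo, hi) range of target-set sizes.
#' @param n_planted_pairs number of family pairs with inflated target
#'   overlap planted as ground truth.
#' @param overlap_multiplier kappa >= 1: planted mean overlap is
#'   `kappa * |A| * |B| / n_genes` (kappa = 1 reproduces independence).
#' @param utr_meanlog,utr_sdlog lognormal parameters of 3'UTR length (nt).
#' @param gc_shape1,gc_shape2 beta parameters of GC fraction.
#' @param phylop_mean,phylop_sd normal parameters of the per-gene phyloP
#'   conservation score.
#' @param utr_bias exponent of the UTR-length weighting of target-gene
#'   inclusion (1 = probability proportional to length; 0 = uniform).
#' @param n_modules number of co-expression modules.
#' @param stages ordered character vector of developmental stages.
#' @param replicates_per_stage samples per stage (alternating sex labels).
#' @param nb_dispersion negative-binomial size parameter (larger = closer
#'   to Poisson; `Inf` selects exact Poisson sampling).
#' @param lib_size_meanlog,lib_size_sdlog lognormal library-size parameters.
#' @param baseline_meanlog,baseline_sdlog lognormal parameters of per-miRNA
#'   baseline abundance (CPM scale).
#' @param conserved_fraction fraction of target interactions flagged conserved.
#' @param plant_near_identical_seeds number of family pairs planted at seed
#'   Hamming distance 1 (to exercise the a-priori exclusion rule).
#' @param rng_seed integer seed; identical config + seed gives identical output.
#'
#' @return a validated list of class `SimConfig`.
#' @examples
#' cfg <- simConfig(n_genes = 500, n_families = 6, rng_seed = 1)
#' @export
simConfig <- function(n_genes = 5000,
                      n_families = 40,
                      members_per_family = c(1, 3),
                      targets_per_family = c(300, 400),
                      n_planted_pairs = 0,
                      overlap_multiplier = 3,
                      utr_meanlog = 7, utr_sdlog = 0.6,
                      gc_shape1 = 40, gc_shape2 = 45,
                      phylop_mean = 1, phylop_sd = 0.3,
                      utr_bias = 1,
                      n_modules = 4,
                      stages = c("E14", "E17", "P0"),
                      replicates_per_stage = 4,
                      nb_dispersion = 10,
                      lib_size_meanlog = log(2e7), lib_size_sdlog = 0.15,
                      baseline_meanlog = log(150), baseline_sdlog = 1,
                      conserved_fraction = 1,
                      plant_near_identical_seeds = 0,
                      rng_seed = 1L) {
  cfg <- list(
    n_genes = as.integer(n_genes), n_families = as.integer(n_families),
    members_per_family = members_per_family,
    targets_per_family = targets_per_family,
    n_planted_pairs = as.integer(n_planted_pairs),
    overlap_multiplier = overlap_multiplier,
    utr_meanlog = utr_meanlog, utr_sdlog = utr_sdlog,
    gc_shape1 = gc_shape1, gc_shape2 = gc_shape2,
    phylop_mean = phylop_mean, phylop_sd = phylop_sd,
    utr_bias = utr_bias,
    n_modules = as.integer(n_modules),
    stages = as.character(stages),
    replicates_per_stage = as.integer(replicates_per_stage),
    nb_dispersion = nb_dispersion,
    lib_size_meanlog = lib_size_meanlog, lib_size_sdlog = lib_size_sdlog,
    baseline_meanlog = baseline_meanlog, baseline_sdlog = baseline_sdlog,
    conserved_fraction = conserved_fraction,
    plant_near_identical_seeds = as.integer(plant_near_identical_seeds),
    rng_seed = as.integer(rng_seed)
  )
  if (cfg$n_genes < 1) .cfgStop("n_genes must be >= 1")
  if (cfg$n_families < 1) .cfgStop("n_families must be >= 1")
  if (cfg$n_families > 4^.SEED_LENGTH)
    .cfgStop("more families than distinct %d-nt seeds", .SEED_LENGTH)
  if (!length(members_per_family) %in% c(1:2, cfg$n_families) ||
      any(members_per_family < 1))
    .cfgStop("members_per_family must be a positive scalar, range, or per-family vector")
  if (!length(targets_per_family) %in% c(1:2, cfg$n_families) ||
      any(targets_per_family < 1))
    .cfgStop("targets_per_family must be a positive scalar, range, or per-family vector")
  if (max(targets_per_family) > cfg$n_genes)
    .cfgStop("targets_per_family exceeds n_genes")
  if (cfg$n_planted_pairs < 0) .cfgStop("n_planted_pairs must be >= 0")
  if (2 * cfg$n_planted_pairs > cfg$n_families)
    .cfgStop("not enough families for %d disjoint planted pairs",
             cfg$n_planted_pairs)
  if (overlap_multiplier < 1) .cfgStop("overlap_multiplier must be >= 1")
  tmax <- max(targets_per_family); tmin <- min(targets_per_family)
  if (cfg$n_planted_pairs > 0 &&
      overlap_multiplier * tmax * tmax / cfg$n_genes > tmin)
    .cfgStop("expected planted overlap kappa*|A|*|B|/n_genes exceeds min(|A|,|B|)")
  if (utr_sdlog <= 0 || gc_shape1 <= 0 || gc_shape2 <= 0 || phylop_sd <= 0)
    .cfgStop("distribution parameters must be positive")
  if (utr_bias < 0) .cfgStop("utr_bias must be >= 0")
  if (cfg$n_modules < 1) .cfgStop("n_modules must be >= 1")
  if (length(cfg$stages) < 1) .cfgStop("at least one stage required")
  if (cfg$replicates_per_stage < 1) .cfgStop("replicates_per_stage must be >= 1")
  if (is.na(nb_dispersion) || nb_dispersion <= 0)
    .cfgStop("nb_dispersion must be positive (Inf selects Poisson)")
  if (conserved_fraction < 0 || conserved_fraction > 1)
    .cfgStop("conserved_fraction must lie in [0, 1]")
  class(cfg) <- "SimConfig"
  cfg
}

#' Generate per-gene 3'UTR features
#'
#' Draws, for each gene, a 3'UTR length (lognormal), GC fraction (beta) and
#' phyloP conservation score (normal) — the three features the matched
#' control selection conditions on.
#'
#' @param config a [simConfig()].
#' @param seed integer RNG seed (defaults to the config's).
#' @return data.frame with columns `gene_id`, `utr_length`, `gc`, `phylop`.
#' @export
generateGeneFeatures <- function(config, seed = config$rng_seed) {
  stopifnot(inherits(config, "SimConfig"))
  set.seed(.subSeed(seed, 1L))
  n <- config$n_genes
  data.frame(
    gene_id = sprintf("gene%05d", seq_len(n)),
    utr_length = rlnorm(n, config$utr_meanlog, config$utr_sdlog),
    gc = rbeta(n, config$gc_shape1, config$gc_shape2),
    phylop = rnorm(n, config$phylop_mean, config$phylop_sd),
    stringsAsFactors = FALSE
  )
}

# distinct random seeds with pairwise Hamming distance >= 2 so no
# accidental pair triggers the near-identical-seed exclusion
.drawSeeds <- function(n) {
  seeds <- character(0)
  attempts <- 0L
  while (length(seeds) < n) {
    s <- paste(sample(.SEED_ALPHABET, .SEED_LENGTH, replace = TRUE),
               collapse = "")
    ok <- !length(seeds) || all(vapply(seeds, function(x)
      seedHamming(x, s) >= 2L, integer(1)))
    if (ok) seeds <- c(seeds, s)
    attempts <- attempts + 1L
    if (attempts > 1000L * n)
      stop("could not draw ", n, " seeds at pairwise distance >= 2", call. = FALSE)
  }
  seeds
}

.mutateSeed <- function(seed, pos) {
  chars <- strsplit(seed, "")[[1]]
  chars[pos] <- sample(setdiff(.SEED_ALPHABET, chars[pos]), 1)
  paste(chars, collapse = "")
}

#' Generate a miRNA catalog with seed families
#'
#' Each family receives a distinct 7-nt seed over {A,U,C,G} (pairwise
#' Hamming distance >= 2 by construction) and one or more member miRNAs
#' sharing that seed. Optionally plants family pairs at seed distance 1 to
#' exercise the a-priori exclusion of near-identical seeds.
#'
#' @inheritParams generateGeneFeatures
#' @return data.frame with one row per miRNA: `mirna_id`, `family_id`,
#'   `seed`, `conserved`.
#' @export
generateCatalog <- function(config, seed = config$rng_seed) {
  stopifnot(inherits(config, "SimConfig"))
  set.seed(.subSeed(seed, 2L))
  nf <- config$n_families
  fam_ids <- sprintf("fam%03d", seq_len(nf))
  seeds <- .drawSeeds(nf)
  npl <- config$plant_near_identical_seeds
  if (npl > 0) {
    if (2 * npl > nf)
      .cfgStop("not enough families for %d near-identical seed pairs", npl)
    for (k in seq_len(npl)) {
      i <- 2L * k - 1L
      seeds[i + 1L] <- .mutateSeed(seeds[i], sample.int(.SEED_LENGTH, 1))
    }
  }
  members <- .drawSizes(config$members_per_family, nf)
  data.frame(
    mirna_id = unlist(lapply(seq_len(nf), function(i)
      sprintf("sim-miR-%03d-%d", i, seq_len(members[i])))),
    family_id = rep(fam_ids, members),
    seed = rep(seeds, members),
    conserved = TRUE,
    stringsAsFactors = FALSE
  )
}

#' Generate family target sets with planted co-targeting pairs
#'
#' Samples each family's target genes without replacement with inclusion
#' probability proportional to `utr_length^utr_bias` (longer 3'UTRs harbour
#' more sites, so they accumulate more targeting families). For each planted
#' pair (A, B) the shared-target count is drawn binomially with mean
#' `kappa * |A| * |B| / n_genes`; the shared genes are assigned to both
#' families and the remainders are drawn from disjoint pools, so the
#' realised overlap equals the drawn count exactly and marginal set sizes
#' stay exact.
#'
#' @inheritParams generateGeneFeatures
#' @param features output of [generateGeneFeatures()].
#' @param catalog_df output of [generateCatalog()].
#' @return list with `targets` (named list family -> gene ids),
#'   `conserved` (parallel logical list) and `truth` (data.frame of planted
#'   pairs: `family_a`, `family_b`, `kappa`, `n_shared`, `expected_shared`).
#' @export
generateTargetSets <- function(config, features, catalog_df,
                               seed = config$rng_seed) {
  stopifnot(inherits(config, "SimConfig"))
  set.seed(.subSeed(seed, 3L))
  fams <- unique(catalog_df$family_id)
  genes <- features$gene_id
  G <- length(genes)
  w <- if (config$utr_bias == 0) rep(1, G) else features$utr_length^config$utr_bias
  sizes <- .drawSizes(config$targets_per_family, length(fams))
  names(sizes) <- fams

  targets <- vector("list", length(fams))
  names(targets) <- fams

  npl <- config$n_planted_pairs
  kappa <- config$overlap_multiplier
  planted <- if (npl > 0) {
    idx <- sample(seq_along(fams), 2L * npl)
    data.frame(family_a = fams[idx[seq_len(npl) * 2L - 1L]],
               family_b = fams[idx[seq_len(npl) * 2L]],
               stringsAsFactors = FALSE)
  } else {
    data.frame(family_a = character(0), family_b = character(0))
  }
  truth <- data.frame(family_a = character(0), family_b = character(0),
                      kappa = numeric(0), n_shared = integer(0),
                      expected_shared = numeric(0), stringsAsFactors = FALSE)

  for (k in seq_len(nrow(planted))) {
    fa <- planted$family_a[k]; fb <- planted$family_b[k]
    na_ <- sizes[[fa]]; nb_ <- sizes[[fb]]
    mu <- kappa * na_ * nb_ / G
    cap <- min(na_, nb_)
    if (mu > cap) .cfgStop("infeasible overlap_multiplier for planted pair")
    s <- rbinom(1L, cap, mu / cap)
    shared_idx <- sample.int(G, s, prob = w)
    rest <- setdiff(seq_len(G), shared_idx)
    a_rest <- rest[sample.int(length(rest), na_ - s, prob = w[rest])]
    rest_b <- setdiff(rest, a_rest)
    b_rest <- rest_b[sample.int(length(rest_b), nb_ - s, prob = w[rest_b])]
    targets[[fa]] <- sort(genes[c(shared_idx, a_rest)])
    targets[[fb]] <- sort(genes[c(shared_idx, b_rest)])
    truth <- rbind(truth, data.frame(
      family_a = fa, family_b = fb, kappa = kappa, n_shared = s,
      expected_shared = mu, stringsAsFactors = FALSE))
  }
  for (f in fams[!fams %in% c(planted$family_a, planted$family_b)]) {
    targets[[f]] <- sort(genes[sample.int(G, sizes[[f]], prob = w)])
  }
  conserved <- lapply(targets, function(tg) {
    if (config$conserved_fraction >= 1) rep(TRUE, length(tg))
    else runif(length(tg)) < config$conserved_fraction
  })
  list(targets = targets, conserved = conserved, truth = truth)
}

#' Module labels and stage profiles
#'
#' Assigns families to modules round-robin (all members of a family share
#' its module) and builds per-module stage profiles cycling through four
#' canonical shapes: decreasing, increasing, peaked and flat mean
#' multipliers across the ordered stages.
#'
#' @inheritParams generateTargetSets
#' @return list with `assignments` (named character, miRNA -> module) and
#'   `profiles` (matrix module x stage of mean multipliers).
#' @export
assignModules <- function(config, catalog_df) {
  stopifnot(inherits(config, "SimConfig"))
  nm <- config$n_modules
  labels <- if (nm <= length(.MODULE_COLORS)) .MODULE_COLORS[seq_len(nm)]
            else c(.MODULE_COLORS,
                   sprintf("module%02d", seq_len(nm - length(.MODULE_COLORS))))
  fams <- unique(catalog_df$family_id)
  fam_module <- setNames(labels[(seq_along(fams) - 1L) %% nm + 1L], fams)
  assignments <- setNames(fam_module[catalog_df$family_id], catalog_df$mirna_id)

  S <- length(config$stages)
  shapes <- rbind(
    down = 2^(rev(seq_len(S)) - 1L),
    up   = 2^(seq_len(S) - 1L),
    peak = 2^pmin(seq_len(S) - 1L, rev(seq_len(S)) - 1L),
    flat = rep(1, S)
  )
  profiles <- shapes[(seq_len(nm) - 1L) %% 4L + 1L, , drop = FALSE]
  rownames(profiles) <- labels
  colnames(profiles) <- config$stages
  list(assignments = assignments, profiles = profiles)
}

#' Generate a stage-structured miRNA count matrix
#'
#' Counts are negative binomial around library-size-scaled means: each
#' miRNA's baseline abundance (lognormal, CPM scale) is multiplied by its
#' module's stage profile and by the sample's library size / 1e6. With
#' `nb_dispersion = Inf` sampling is exactly Poisson.
#'
#' @inheritParams generateTargetSets
#' @param assignments,profiles output of [assignModules()].
#' @return list with `counts` (integer matrix, miRNA x sample) and
#'   `metadata` (data.frame: `sample_id`, `stage`, `sex`, `replicate`,
#'   `lib_size`).
#' @export
generateCounts <- function(config, catalog_df, assignments, profiles,
                           seed = config$rng_seed) {
  stopifnot(inherits(config, "SimConfig"))
  set.seed(.subSeed(seed, 4L))
  stages <- config$stages
  reps <- config$replicates_per_stage
  metadata <- do.call(rbind, lapply(stages, function(st) {
    sex <- rep_len(c("F", "M"), reps)
    data.frame(sample_id = sprintf("%s_%s%d", st, sex,
                                   stats::ave(seq_len(reps), sex, FUN = seq_along)),
               stage = st, sex = sex, replicate = seq_len(reps),
               stringsAsFactors = FALSE)
  }))
  metadata$lib_size <- rlnorm(nrow(metadata), config$lib_size_meanlog,
                              config$lib_size_sdlog)
  mirnas <- catalog_df$mirna_id
  baseline <- rlnorm(length(mirnas), config$baseline_meanlog,
                     config$baseline_sdlog)
  prof <- profiles[assignments[mirnas], metadata$stage, drop = FALSE]
  mu <- baseline * prof * rep(metadata$lib_size / 1e6, each = length(mirnas))
  n <- length(mu)
  counts <- if (is.infinite(config$nb_dispersion)) {
    rpois(n, lambda = mu)
  } else {
    rnbinom(n, mu = mu, size = config$nb_dispersion)
  }
  counts <- matrix(as.integer(counts), nrow = length(mirnas),
                   dimnames = list(mirnas, metadata$sample_id))
  list(counts = counts, metadata = metadata)
}

#' Generate a complete synthetic study
#'
#' Orchestrates [generateGeneFeatures()], [generateCatalog()],
#' [generateTargetSets()], [assignModules()] and [generateCounts()] into a
#' [StudyBundle-class]. The output is a pure function of (config, seed):
#' identical inputs give identical bundles.
#'
#' @inheritParams generateGeneFeatures
#' @return a [StudyBundle-class].
#' @examples
#' bundle <- generateStudy(simConfig(n_genes = 400, n_families = 6,
#'                                   targets_per_family = c(30, 60),
#'                                   rng_seed = 7))
#' @export
generateStudy <- function(config, seed = config$rng_seed) {
  stopifnot(inherits(config, "SimConfig"))
  features <- generateGeneFeatures(config, seed)
  catalog_df <- generateCatalog(config, seed)
  ts <- generateTargetSets(config, features, catalog_df, seed)
  mods <- assignModules(config, catalog_df)
  cnt <- generateCounts(config, catalog_df, mods$assignments, mods$profiles, seed)

  cat_obj <- new("TargetCatalog",
                 mirnas = catalog_df,
                 targets = ts$targets,
                 target_conserved = ts$conserved,
                 features = features)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = cnt$counts),
    colData = S4Vectors::DataFrame(cnt$metadata[, -1], row.names = cnt$metadata$sample_id),
    rowData = S4Vectors::DataFrame(
      family_id = catalog_df$family_id,
      seed = catalog_df$seed,
      module = unname(mods$assignments[catalog_df$mirna_id]),
      row.names = catalog_df$mirna_id)
  )
  new("StudyBundle", se,
      catalog = cat_obj,
      moduleAssignments = mods$assignments,
      truth = list(planted_pairs = ts$truth, module_profiles = mods$profiles,
                   config = config, seed = as.integer(seed)))
}
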