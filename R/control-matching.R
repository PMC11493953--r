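## Matched-control construction: per family, each target gene is paired
## with a randomly chosen control gene of similar 3'UTR length, GC content
## and phyloP score, via three multiplicative feature windows.

#' Matching configuration
#'
#' Multiplicative case-control windows: a candidate control is retained for
#' a target gene with feature value t iff its value lies in
#' `[min, max](lo * t, hi * t)` for all three features (interval endpoints
#' ordered so negative phyloP targets remain well-defined; endpoints
#' inclusive).
#'
#' @param utr_window 3'UTR-length window (default `c(0.85, 1.15)`).
#' @param gc_window GC-content window (default `c(0.95, 1.05)`).
#' @param phylop_window phyloP window (default `c(0.8, 1.2)`).
#' @param reuse_policy `"without_replacement"` (controls distinct within a
#'   family, the default) or `"with_replacement"`.
#' @param candidate_pool `"all_non_targets"` (default: controls are drawn
#'   from genes outside the family's own target set) or `"all_genes"`.
#' @param rng_seed base integer seed; per-family substreams are derived by
#'   hashing the family id so results do not depend on processing order.
#' @return a validated list of class `MatchingConfig`.
#' @export
matchingConfig <- function(utr_window = c(0.85, 1.15),
                           gc_window = c(0.95, 1.05),
                           phylop_window = c(0.8, 1.2),
                           reuse_policy = c("without_replacement",
                                            "with_replacement"),
                           candidate_pool = c("all_non_targets", "all_genes"),
                           rng_seed = 1L) {
  for (w in list(utr_window, gc_window, phylop_window)) {
    if (length(w) != 2L || any(w <= 0) || w[1] >= w[2])
      stop("each window must be positive bounds with lower < upper",
           call. = FALSE)
  }
  cfg <- list(utr_window = utr_window, gc_window = gc_window,
              phylop_window = phylop_window,
              reuse_policy = match.arg(reuse_policy),
              candidate_pool = match.arg(candidate_pool),
              rng_seed = as.integer(rng_seed))
  class(cfg) <- "MatchingConfig"
  cfg
}

# orientation-normalized multiplicative interval test (inclusive endpoints)
.inWindow <- function(values, t, window) {
  lo <- pmin(window[1] * t, window[2] * t)
  hi <- pmax(window[1] * t, window[2] * t)
  values >= lo & values <= hi
}

#' Candidate controls for one target gene
#'
#' Applies the three multiplicative windows of `config` relative to the
#' target's feature values. An empty result is a valid outcome (the target
#' is then recorded as having no control).
#'
#' @param target single-row data.frame (or list) with `utr_length`, `gc`,
#'   `phylop`.
#' @param pool data.frame of candidate genes with `gene_id` and the three
#'   feature columns.
#' @param config a [matchingConfig()].
#' @return character vector of candidate gene ids.
#' @export
candidateFilter <- function(target, pool, config = matchingConfig()) {
  stopifnot(inherits(config, "MatchingConfig"))
  keep <- .inWindow(pool$utr_length, target$utr_length, config$utr_window) &
    .inWindow(pool$gc, target$gc, config$gc_window) &
    .inWindow(pool$phylop, target$phylop, config$phylop_window)
  pool$gene_id[keep]
}

#' Build the matched control set for one family
#'
#' Iterates the family's target genes in lexicographic order; for each,
#' filters the candidate pool through the three windows, removes controls
#' already used (under `without_replacement`), and picks one uniformly at
#' random. Targets with an empty candidate set are recorded with an absent
#' (`NA`) control. Deterministic given `config$rng_seed` (per-family
#' substream derived from the family id).
#'
#' @param family_id family identifier (also seeds the RNG substream).
#' @param target_genes character vector of the family's target genes.
#' @param features data.frame of per-gene features covering all genes.
#' @param config a [matchingConfig()].
#' @return a [ControlSet-class].
#' @export
buildControlSet <- function(family_id, target_genes, features,
                            config = matchingConfig()) {
  stopifnot(inherits(config, "MatchingConfig"))
  target_genes <- sort(unique(target_genes))
  idx <- match(target_genes, features$gene_id)
  if (anyNA(idx))
    stop("missing features for target gene(s): ",
         paste(head(target_genes[is.na(idx)], 3), collapse = ", "),
         call. = FALSE)
  pool <- if (config$candidate_pool == "all_non_targets") {
    features[!features$gene_id %in% target_genes, , drop = FALSE]
  } else features
  set.seed(.subSeed(config$rng_seed, 11L, family_id))

  p_utr <- pool$utr_length; p_gc <- pool$gc; p_phy <- pool$phylop
  p_id <- pool$gene_id
  t_utr <- features$utr_length[idx]
  t_gc <- features$gc[idx]
  t_phy <- features$phylop[idx]
  available <- rep(TRUE, nrow(pool))
  controls <- rep(NA_character_, length(target_genes))
  for (i in seq_along(target_genes)) {
    cand <- .inWindow(p_utr, t_utr[i], config$utr_window) &
      .inWindow(p_gc, t_gc[i], config$gc_window) &
      .inWindow(p_phy, t_phy[i], config$phylop_window)
    if (config$reuse_policy == "without_replacement") cand <- cand & available
    ci <- which(cand)
    if (length(ci)) {
      pick <- ci[sample.int(length(ci), 1L)]
      controls[i] <- p_id[pick]
      if (config$reuse_policy == "without_replacement") available[pick] <- FALSE
    }
  }
  new("ControlSet", family_id = family_id,
      pairs = data.frame(target_gene = target_genes, control_gene = controls,
                         stringsAsFactors = FALSE))
}

#' Build control sets for every family of a catalog
#'
#' @param catalog a [TargetCatalog-class] (its `features` slot must cover
#'   all target genes).
#' @param config a [matchingConfig()].
#' @return named list of [ControlSet-class] objects, one per family.
#' @export
buildControlSets <- function(catalog, config = matchingConfig()) {
  stopifnot(is(catalog, "TargetCatalog"))
  features <- catalog@features
  if (!nrow(features)) stop("catalog has no gene features", call. = FALSE)
  fams <- names(catalog@targets)
  out <- lapply(fams, function(f)
    buildControlSet(f, catalog@targets[[f]], features, config))
  names(out) <- fams
  out
}

#' Validate target/control distributional similarity
#'
#' Two-sample Wilcoxon rank-sum tests comparing the matched targets'
#' and controls' 3'UTR length, GC content and phyloP distributions.
#' Non-significant p-values indicate successful matching; features with
#' p <= 0.05 are flagged.
#'
#' @param control_set a [ControlSet-class].
#' @param features data.frame of per-gene features.
#' @param min_pairs minimum number of matched pairs required (default 8).
#' @return data.frame with columns `feature`, `p_value`, `flagged`.
#' @export
validateMatching <- function(control_set, features, min_pairs = 8L) {
  stopifnot(is(control_set, "ControlSet"))
  pairs <- control_set@pairs
  pairs <- pairs[!is.na(pairs$control_gene), , drop = FALSE]
  if (nrow(pairs) < min_pairs)
    stop("insufficient matched pairs (", nrow(pairs), " < ", min_pairs, ")",
         call. = FALSE)
  ti <- match(pairs$target_gene, features$gene_id)
  ci <- match(pairs$control_gene, features$gene_id)
  if (anyNA(ti) || anyNA(ci))
    stop("features missing for matched genes", call. = FALSE)
  feats <- c("utr_length", "gc", "phylop")
  p <- vapply(feats, function(f) {
    suppressWarnings(wilcox.test(features[[f]][ti], features[[f]][ci],
                                 exact = FALSE)$p.value)
  }, numeric(1))
  data.frame(feature = feats, p_value = unname(p),
             flagged = unname(p) <= 0.05, stringsAsFactors = FALSE,
             row.names = NULL)
}
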