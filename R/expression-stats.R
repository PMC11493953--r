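## Expression-level utilities: CPM and low-expression filtering, DE
## classification of externally produced result tables, DE-target
## enrichment (generalized exact test), overlap summaries, normalizations
## and delta-delta-CT relative quantification.

#' Counts per million
#'
#' `count / library_size * 1e6` per cell, with library size taken as the
#' column sum of the count matrix.
#'
#' @param counts non-negative numeric matrix (features x samples).
#' @return CPM matrix of the same dimensions.
#' @export
cpm <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  lib <- colSums(counts)
  if (any(lib == 0))
    stop("zero library size in sample(s): ",
         paste(head(colnames(counts)[lib == 0], 3), collapse = ", "),
         call. = FALSE)
  sweep(counts, 2, lib, "/") * 1e6
}

#' Low-expression filter
#'
#' Retains features with CPM strictly above `min_cpm` in at least
#' `min_samples` samples.
#'
#' @param cpm_mat CPM matrix (see [cpm()]).
#' @param min_cpm CPM threshold (default 10, strict inequality).
#' @param min_samples minimum number of samples above threshold (default 5).
#' @return character vector of retained feature ids.
#' @export
filterLowExpression <- function(cpm_mat, min_cpm = 10, min_samples = 5L) {
  cpm_mat <- as.matrix(cpm_mat)
  if (min_samples > ncol(cpm_mat))
    stop("min_samples exceeds the number of samples", call. = FALSE)
  keep <- rowSums(cpm_mat > min_cpm) >= min_samples
  rownames(cpm_mat)[keep]
}

#' Classify differential-expression results
#'
#' `up` iff `padj < alpha` and `log2fc > lfc`; `down` iff `padj < alpha`
#' and `log2fc < -lfc`; otherwise `ns`. Thresholds are strict (a fold
#' change of exactly `lfc` is not differentially expressed).
#'
#' @param de data.frame with columns `id`, `log2fc`, `padj`.
#' @param alpha adjusted p-value threshold (default 0.05).
#' @param lfc absolute log2-fold-change threshold (default 0.5).
#' @return the input with a `de_class` factor column (`up`/`down`/`ns`).
#' @export
classifyDE <- function(de, alpha = 0.05, lfc = 0.5) {
  need <- c("id", "log2fc", "padj")
  missing_cols <- setdiff(need, names(de))
  if (length(missing_cols))
    .fmtStop("DE table missing column(s): %s",
             paste(missing_cols, collapse = ", "))
  if (any(de$padj < 0 | de$padj > 1, na.rm = TRUE))
    stop("padj must lie in [0, 1]", call. = FALSE)
  cls <- rep("ns", nrow(de))
  sig <- !is.na(de$padj) & de$padj < alpha
  cls[sig & de$log2fc > lfc] <- "up"
  cls[sig & de$log2fc < -lfc] <- "down"
  de$de_class <- factor(cls, levels = c("up", "down", "ns"))
  de
}

# log conditional probability of 2xC tables with fixed margins
# (multivariate hypergeometric in the first row)
.logProbTable <- function(row1, col_totals, N, r1) {
  sum(lchoose(col_totals, row1)) - lchoose(N, r1)
}

#' DE-target enrichment (generalized exact test)
#'
#' Builds the 2x3 contingency table of DE classes (up/down/ns) for a target
#' gene set against all other genes and computes an exact conditional
#' p-value (generalized Fisher's exact test: total probability of tables
#' with fixed margins no more probable than the observed one). Tables with
#' total `N <= enumeration_limit` are fully enumerated; larger tables use a
#' Monte-Carlo estimate over `mc_reps` tables drawn with fixed margins and
#' a fixed seed. Per-column 2x2 odds ratios (one class versus the rest) are
#' reported alongside.
#'
#' @param de a classified DE table (see [classifyDE()]) covering the gene
#'   universe.
#' @param target_genes character vector of target gene ids (non-empty).
#' @param enumeration_limit switch point between full enumeration and
#'   Monte-Carlo (default 500).
#' @param mc_reps Monte-Carlo replicates (default 10000).
#' @param seed RNG seed for the Monte-Carlo branch (default 1).
#' @return list with `table` (2x3 matrix), `p`, `method`
#'   (`"enumeration"` or `"monte-carlo"`), `mc_reps` (NA for enumeration),
#'   `column_or` (named per-class odds ratios, Haldane-corrected).
#' @export
targetDEEnrichment <- function(de, target_genes, enumeration_limit = 500,
                               mc_reps = 10000L, seed = 1L) {
  if (length(target_genes) == 0)
    stop("target gene set is empty", call. = FALSE)
  if (!"de_class" %in% names(de)) de <- classifyDE(de)
  is_target <- de$id %in% target_genes
  lev <- c("up", "down", "ns")
  tab <- rbind(
    target = table(factor(de$de_class[is_target], levels = lev)),
    background = table(factor(de$de_class[!is_target], levels = lev)))
  tab <- matrix(as.numeric(tab), nrow = 2, dimnames = dimnames(tab))

  N <- sum(tab); r1 <- sum(tab[1, ]); cols <- colSums(tab)
  lp_obs <- .logProbTable(tab[1, ], cols, N, r1)
  eps <- 1e-7
  if (r1 == 0 || r1 == N || all(cols == 0)) {
    p <- 1; method <- "enumeration"; reps <- NA_integer_
  } else if (N <= enumeration_limit) {
    p <- 0
    base <- -lchoose(N, r1)
    for (a1 in 0:min(r1, cols[1])) {
      a2 <- max(0, r1 - a1 - cols[3]):min(r1 - a1, cols[2])
      a2 <- a2[a2 >= 0]
      if (!length(a2)) next
      lp <- base + lchoose(cols[1], a1) + lchoose(cols[2], a2) +
        lchoose(cols[3], r1 - a1 - a2)
      p <- p + sum(exp(lp[lp <= lp_obs + eps]))
    }
    p <- min(1, p)
    method <- "enumeration"; reps <- NA_integer_
  } else {
    set.seed(.subSeed(seed, 21L))
    sim <- r2dtable(mc_reps, c(r1, N - r1), cols)
    lps <- vapply(sim, function(m) .logProbTable(m[1, ], cols, N, r1),
                  numeric(1))
    p <- (1 + sum(lps <= lp_obs + eps)) / (mc_reps + 1)
    method <- "monte-carlo"; reps <- as.integer(mc_reps)
  }
  column_or <- vapply(seq_len(3), function(j) {
    cells <- c(tab[1, j], sum(tab[1, -j]), tab[2, j], sum(tab[2, -j]))
    if (any(cells == 0)) cells <- cells + 0.5
    (cells[1] * cells[4]) / (cells[2] * cells[3])
  }, numeric(1))
  names(column_or) <- lev
  list(table = tab, p = p, method = method, mc_reps = reps,
       column_or = column_or)
}

.halfUp <- function(x) floor(x + 0.5)

#' Overlap summary of two id sets
#'
#' Intersection size and the percentage of each set covered, rounded
#' half-up to integers (as printed in results text). An empty denominator
#' set yields `NA` for its percentage.
#'
#' @param set_a,set_b character vectors of ids.
#' @return list with `n_a`, `n_b`, `n_common`, `pct_of_a`, `pct_of_b`.
#' @examples
#' # "(73 out of 113)" -> 65%
#' summarizeDEOverlap(paste0("x", 1:113), paste0("x", 1:73))$pct_of_a
#' @export
summarizeDEOverlap <- function(set_a, set_b) {
  a <- unique(set_a); b <- unique(set_b)
  nc <- length(intersect(a, b))
  list(n_a = length(a), n_b = length(b), n_common = nc,
       pct_of_a = if (length(a)) .halfUp(100 * nc / length(a)) else NA_real_,
       pct_of_b = if (length(b)) .halfUp(100 * nc / length(b)) else NA_real_)
}

#' Z-score or min-max normalization
#'
#' `zscore`: `(v - mean) / sd` (sample sd, n-1 denominator);
#' `minmax`: `(v - min) / (max - min)`, mapping onto `[0, 1]` with the
#' endpoints attained.
#'
#' @param values numeric vector of length >= 2, non-constant.
#' @param mode `"zscore"` or `"minmax"`.
#' @return normalized numeric vector.
#' @export
normalizeValues <- function(values, mode = c("zscore", "minmax")) {
  mode <- match.arg(mode)
  if (length(values) < 2) stop("need at least 2 values", call. = FALSE)
  if (max(values) == min(values))
    stop("constant input: normalization undefined", call. = FALSE)
  if (mode == "zscore") (values - mean(values)) / sd(values)
  else (values - min(values)) / (max(values) - min(values))
}

#' Relative quantification by the delta-delta-CT method
#'
#' `RQ = 2^-((ct_target - ct_reference) - (ct_target_cal - ct_reference_cal))`:
#' the experimental sample's target CT normalized to its reference gene
#' (e.g. U6 snRNA), relative to the calibrator sample's normalized CT.
#'
#' @param ct_target,ct_reference CT values in the experimental sample.
#' @param ct_target_cal,ct_reference_cal CT values in the calibrator sample.
#' @return positive RQ value(s); vectorized.
#' @export
deltaDeltaCt <- function(ct_target, ct_reference, ct_target_cal,
                         ct_reference_cal) {
  stopifnot(all(is.finite(c(ct_target, ct_reference, ct_target_cal,
                            ct_reference_cal))))
  ddct <- (ct_target - ct_reference) - (ct_target_cal - ct_reference_cal)
  2^(-ddct)
}
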