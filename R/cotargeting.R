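## The central statistic: bidirectional Fisher's exact tests of shared
## target counts against the matched-control null, BH adjustment, odds
## ratios, and co-targeting network assembly with its summaries.

.checkTable <- function(tab) {
  if (is.matrix(tab)) tab <- as.vector(t(tab))
  if (length(tab) != 4L) stop("need a 2x2 table (a, b, c, d)", call. = FALSE)
  if (any(tab < 0)) stop("table entries must be non-negative", call. = FALSE)
  if (any(tab != round(tab))) stop("table entries must be integers", call. = FALSE)
  as.numeric(tab)
}

#' One-sided Fisher's exact test (enrichment of shared targets)
#'
#' Exact hypergeometric upper-tail probability `P(X >= a)` conditional on
#' the table margins, for the 2x2 table `[[a, b], [c, d]]` where `a` is the
#' observed shared-target count, `a + b` the target-set size and `c + d`
#' the control-set size. Computed by summing the hypergeometric PMF over
#' the upper support via `lchoose` (numerically exact for desk-scale
#' tables).
#'
#' @param tab 2x2 matrix `rbind(c(a, b), c(c, d))` or numeric vector
#'   `c(a, b, c, d)`.
#' @return the one-sided p-value.
#' @examples
#' fisherGreater(rbind(c(5, 5), c(1, 9)))  # 13013/184756 = 0.0704334
#' @export
fisherGreater <- function(tab) {
  v <- .checkTable(tab)
  a <- v[1]; b <- v[2]; c <- v[3]; d <- v[4]
  N <- a + b + c + d
  K <- a + c          # total "A-target" successes
  n <- a + b          # draws (target set of B)
  hi <- min(K, n)
  if (a > hi) return(0)  # unreachable, defensive
  x <- seq(a, hi)
  logp <- lchoose(K, x) + lchoose(N - K, n - x) - lchoose(N, n)
  min(1, sum(exp(logp)))
}

#' Odds ratio of a 2x2 table with Haldane-Anscombe correction
#'
#' `(a * d) / (b * c)`; when any cell is zero, `continuity` is added to all
#' four cells first so the ratio stays finite.
#'
#' @inheritParams fisherGreater
#' @param continuity value added to every cell when a zero occurs
#'   (default 0.5).
#' @return positive odds ratio.
#' @examples
#' oddsRatio(rbind(c(2, 3), c(1, 4)))  # 8/3
#' @export
oddsRatio <- function(tab, continuity = 0.5) {
  v <- .checkTable(tab)
  if (any(v == 0)) v <- v + continuity
  (v[1] * v[4]) / (v[2] * v[3])
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up false-discovery-rate adjustment (monotone, clipped at
#' 1), after validating that all inputs are probabilities.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return adjusted p-values in input order.
#' @examples
#' bhAdjust(c(0.01, 0.02, 0.03))  # 0.03 0.03 0.03
#' @export
bhAdjust <- function(p) {
  if (!is.numeric(p) || anyNA(p) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  p.adjust(p, method = "BH")
}

# logical gene x family membership matrix over a fixed gene universe
.membershipMatrix <- function(sets, universe) {
  m <- matrix(FALSE, nrow = length(universe), ncol = length(sets),
              dimnames = list(universe, names(sets)))
  for (f in names(sets)) {
    g <- sets[[f]]
    g <- g[!is.na(g)]
    m[match(unique(g), universe), f] <- TRUE
  }
  m
}

#' Detect significant co-targeting pairs
#'
#' For every unordered, non-excluded family pair (A, B) builds the two
#' directional 2x2 tables — shared targets `|T_A intersect T_B|` against
#' the matched-control intersection `|T_A intersect C_B|`, and vice versa —
#' computes both one-sided exact p-values, adjusts all directional p-values
#' in a single Benjamini-Hochberg family (or per direction), and calls a
#' pair significant only when both adjusted p-values fall below `alpha`
#' (bidirectional rule). Odds ratios are Haldane-corrected when a zero cell
#' occurs; the per-pair ranking OR is the geometric mean of the two
#' directional ORs.
#'
#' @param catalog a filtered [TargetCatalog-class].
#' @param control_sets named list of [ControlSet-class], one per family
#'   (see [buildControlSets()]).
#' @param excluded data.frame of family pairs to skip (see
#'   [excludedPairs()]), or `NULL`.
#' @param alpha significance level on the adjusted p-values (default 0.05).
#' @param bh_pooling `"pooled"` (one BH family over all 2P directional
#'   p-values, the default) or `"per_direction"`.
#' @param seed integer recorded in the network's provenance.
#' @return a [CoTargetNetwork-class].
#' @export
detectPairs <- function(catalog, control_sets, excluded = NULL,
                        alpha = 0.05, bh_pooling = c("pooled", "per_direction"),
                        seed = NA_integer_) {
  stopifnot(is(catalog, "TargetCatalog"))
  bh_pooling <- match.arg(bh_pooling)
  fams <- sort(names(catalog@targets))
  if (!all(fams %in% names(control_sets)))
    stop("family without control set: ",
         paste(head(setdiff(fams, names(control_sets)), 3), collapse = ", "),
         call. = FALSE)
  universe <- sort(unique(c(unlist(catalog@targets, use.names = FALSE),
                            unlist(lapply(control_sets, controlGenes),
                                   use.names = FALSE))))
  Tm <- .membershipMatrix(catalog@targets[fams], universe)
  Cm <- .membershipMatrix(lapply(control_sets[fams], controlGenes), universe)
  TT <- crossprod(Tm)            # TT[A, B] = |T_A intersect T_B|
  TC <- crossprod(Tm, Cm)        # TC[A, B] = |T_A intersect C_B|
  t_size <- colSums(Tm)
  c_size <- colSums(Cm)

  pairs <- which(upper.tri(TT), arr.ind = TRUE)
  fa <- fams[pairs[, 1]]; fb <- fams[pairs[, 2]]
  if (!is.null(excluded) && nrow(excluded)) {
    exkey <- paste(pmin(excluded$family_a, excluded$family_b),
                   pmax(excluded$family_a, excluded$family_b))
    keep <- !(paste(pmin(fa, fb), pmax(fa, fb)) %in% exkey)
    pairs <- pairs[keep, , drop = FALSE]
    fa <- fa[keep]; fb <- fb[keep]
  }
  np <- length(fa)
  a <- TT[pairs]
  # direction A->B: targets of A among T_B vs among C_B
  c_ab <- TC[pairs]
  b_ab <- t_size[fb] - a
  d_ab <- c_size[fb] - c_ab
  # direction B->A
  c_ba <- TC[pairs[, c(2, 1), drop = FALSE]]
  b_ba <- t_size[fa] - a
  d_ba <- c_size[fa] - c_ba

  p_ab <- vapply(seq_len(np), function(i)
    fisherGreater(c(a[i], b_ab[i], c_ab[i], d_ab[i])), numeric(1))
  p_ba <- vapply(seq_len(np), function(i)
    fisherGreater(c(a[i], b_ba[i], c_ba[i], d_ba[i])), numeric(1))
  if (bh_pooling == "pooled") {
    q <- bhAdjust(c(p_ab, p_ba))
    q_ab <- q[seq_len(np)]; q_ba <- q[np + seq_len(np)]
  } else {
    q_ab <- bhAdjust(p_ab); q_ba <- bhAdjust(p_ba)
  }
  or_ab <- vapply(seq_len(np), function(i)
    oddsRatio(c(a[i], b_ab[i], c_ab[i], d_ab[i])), numeric(1))
  or_ba <- vapply(seq_len(np), function(i)
    oddsRatio(c(a[i], b_ba[i], c_ba[i], d_ba[i])), numeric(1))

  edges <- data.frame(
    family_a = fa, family_b = fb, n_shared = as.integer(a),
    p_ab = p_ab, p_ba = p_ba, q_ab = q_ab, q_ba = q_ba,
    or_ab = or_ab, or_ba = or_ba,
    or_combined = sqrt(or_ab * or_ba),
    significant = q_ab < alpha & q_ba < alpha,
    stringsAsFactors = FALSE)
  rownames(edges) <- NULL
  sig <- edges[edges$significant, , drop = FALSE]
  deg <- table(factor(c(sig$family_a, sig$family_b), levels = fams))
  members <- table(factor(catalog@mirnas$family_id, levels = fams))
  nodes <- data.frame(family_id = fams,
                      n_members = as.integer(members),
                      degree = as.integer(deg),
                      stringsAsFactors = FALSE)
  new("CoTargetNetwork", edges = edges, nodes = nodes,
      mirna_family = setNames(catalog@mirnas$family_id,
                              catalog@mirnas$mirna_id),
      alpha = alpha, seed = as.integer(seed))
}

#' Per-miRNA degree distribution
#'
#' Each miRNA inherits its family's degree (number of incident significant
#' edges); returns the per-miRNA degrees and their histogram.
#'
#' @param network a [CoTargetNetwork-class].
#' @return list with `degrees` (named integer vector per miRNA) and
#'   `histogram` (table of degree frequencies over miRNAs).
#' @export
degreeDistribution <- function(network) {
  stopifnot(is(network, "CoTargetNetwork"))
  fam_deg <- setNames(network@nodes$degree, network@nodes$family_id)
  degrees <- setNames(as.integer(fam_deg[network@mirna_family]),
                      names(network@mirna_family))
  list(degrees = degrees, histogram = table(degrees))
}

#' Correlation of co-targeting degree with expression level
#'
#' Pearson correlation between per-miRNA degree (family degree broadcast to
#' members) and `log2(mean CPM + pseudocount)`.
#'
#' @param network a [CoTargetNetwork-class].
#' @param expression named numeric vector of per-miRNA mean CPM.
#' @param pseudocount added before the log2 transform (default 1).
#' @return list with `r`, `p`, and `n` (miRNAs used).
#' @export
degreeExpressionCorrelation <- function(network, expression, pseudocount = 1) {
  stopifnot(is(network, "CoTargetNetwork"))
  deg <- degreeDistribution(network)$degrees
  common <- intersect(names(deg), names(expression))
  if (length(common) < 3)
    stop("need expression for at least 3 miRNAs in the network", call. = FALSE)
  x <- deg[common]
  y <- log2(expression[common] + pseudocount)
  if (sd(x) == 0 || sd(y) == 0)
    stop("undefined correlation: zero variance in degree or expression",
         call. = FALSE)
  ct <- cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(common))
}

#' Per-gene counts of significant co-targeting pairs
#'
#' For each gene, the number of significant edges (A, B) whose shared
#' target set contains it; optionally the Pearson correlation of these
#' counts with 3'UTR length.
#'
#' @param network a [CoTargetNetwork-class].
#' @param catalog the [TargetCatalog-class] the network was built from.
#' @return list with `counts` (data.frame `gene_id`, `n_pairs`) and, when
#'   features are available, `utr_correlation` (list `r`, `p`).
#' @export
genePairCounts <- function(network, catalog) {
  stopifnot(is(network, "CoTargetNetwork"), is(catalog, "TargetCatalog"))
  genes <- sort(unique(unlist(catalog@targets, use.names = FALSE)))
  counts <- setNames(integer(length(genes)), genes)
  sig <- significantEdges(network)
  for (i in seq_len(nrow(sig))) {
    shared <- intersect(catalog@targets[[sig$family_a[i]]],
                        catalog@targets[[sig$family_b[i]]])
    counts[shared] <- counts[shared] + 1L
  }
  out <- list(counts = data.frame(gene_id = genes, n_pairs = unname(counts),
                                  stringsAsFactors = FALSE))
  feat <- catalog@features
  if (nrow(feat)) {
    idx <- match(genes, feat$gene_id)
    ok <- !is.na(idx)
    if (sum(ok) >= 3 && sd(counts[ok]) > 0) {
      ct <- cor.test(counts[ok], feat$utr_length[idx[ok]], method = "pearson")
      out$utr_correlation <- list(r = unname(ct$estimate), p = ct$p.value)
    }
  }
  out
}

#' Strongest co-targeting relationships
#'
#' The `k` significant edges with the largest combined odds ratio
#' (geometric mean of the directional ORs), ties broken lexicographically
#' by (family_a, family_b) for stability across runs.
#'
#' @param network a [CoTargetNetwork-class].
#' @param k number of edges to return (default 10; all edges when fewer).
#' @return data.frame of edges sorted by decreasing `or_combined`.
#' @export
topPairs <- function(network, k = 10) {
  stopifnot(is(network, "CoTargetNetwork"))
  if (k < 1) stop("k must be >= 1", call. = FALSE)
  sig <- significantEdges(network)
  o <- order(-sig$or_combined, sig$family_a, sig$family_b)
  sig <- sig[o, , drop = FALSE]
  rownames(sig) <- NULL
  head(sig, k)
}
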