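## Module-level statistics for co-expression modules: eigengenes (first
## principal component of the standardized module expression matrix),
## module-trait correlation, module membership, trait significance, and
## the intra- vs inter-modular co-targeting association test.

.zscoreRows <- function(mat) {
  mu <- rowMeans(mat)
  s <- apply(mat, 1, sd)
  if (any(s == 0))
    stop("constant expression row(s): ",
         paste(head(rownames(mat)[s == 0], 3), collapse = ", "),
         call. = FALSE)
  (mat - mu) / s
}

#' Module eigengene
#'
#' First principal-component sample scores of the module's expression
#' matrix after per-miRNA z-scoring (rows standardized), with the sign
#' oriented so the eigengene correlates non-negatively with the module's
#' average standardized profile. The eigengene has unit norm.
#'
#' @param expr numeric matrix (miRNA x sample) of the module's expression
#'   (typically log2 CPM); at least 2 miRNAs and 3 samples.
#' @param orient_to_mean orient the sign to the mean profile (default TRUE).
#' @return list with `eigengene` (named per-sample vector, unit norm) and
#'   `variance_explained` (fraction in `[0, 1]`).
#' @export
moduleEigengene <- function(expr, orient_to_mean = TRUE) {
  expr <- as.matrix(expr)
  if (nrow(expr) < 2 || ncol(expr) < 3)
    stop("need at least 2 miRNAs and 3 samples", call. = FALSE)
  z <- .zscoreRows(expr)
  sv <- svd(z)
  me <- sv$v[, 1]
  names(me) <- colnames(expr)
  if (orient_to_mean) {
    avg <- colMeans(z)
    if (sum(me * avg) < 0) me <- -me
  }
  list(eigengene = me,
       variance_explained = sv$d[1]^2 / sum(sv$d^2))
}

#' Module-trait correlation
#'
#' Pearson correlation between a module eigengene and a per-sample numeric
#' trait (by convention the developmental-stage code, e.g. E14 = 1,
#' E17 = 2, P0 = 3).
#'
#' @param eigengene per-sample numeric vector.
#' @param trait per-sample numeric trait of the same length.
#' @return list with `r` and two-sided `p`.
#' @export
moduleTraitCorrelation <- function(eigengene, trait) {
  stopifnot(length(eigengene) == length(trait))
  if (length(trait) < 3) stop("need at least 3 samples", call. = FALSE)
  if (sd(trait) == 0)
    stop("undefined correlation: constant trait", call. = FALSE)
  if (sd(eigengene) == 0)
    stop("undefined correlation: constant eigengene", call. = FALSE)
  ct <- cor.test(eigengene, trait, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value)
}

#' Stage codes for trait correlations
#'
#' Maps ordered stage labels to equally spaced integer codes (1, 2, ...).
#'
#' @param stage per-sample stage labels.
#' @param levels ordered unique stage labels (default: order of first
#'   appearance).
#' @return numeric vector of codes.
#' @export
stageCodes <- function(stage, levels = unique(stage)) {
  as.numeric(factor(as.character(stage), levels = levels))
}

#' Module membership and trait significance
#'
#' Per miRNA, two Pearson correlations: module membership = correlation of
#' the miRNA's expression with the module eigengene; trait significance =
#' correlation with the per-sample trait.
#'
#' @param expr numeric matrix (miRNA x sample), sample order matching
#'   `eigengene` and `trait`.
#' @param eigengene per-sample module eigengene.
#' @param trait per-sample numeric trait.
#' @return data.frame with columns `mirna_id`, `module_membership`,
#'   `trait_significance`.
#' @export
membershipAndSignificance <- function(expr, eigengene, trait) {
  expr <- as.matrix(expr)
  stopifnot(ncol(expr) == length(eigengene), ncol(expr) == length(trait))
  s <- apply(expr, 1, sd)
  if (any(s == 0))
    stop("constant expression row(s): ",
         paste(head(rownames(expr)[s == 0], 3), collapse = ", "),
         call. = FALSE)
  data.frame(
    mirna_id = rownames(expr),
    module_membership = apply(expr, 1, cor, y = eigengene),
    trait_significance = apply(expr, 1, cor, y = trait),
    stringsAsFactors = FALSE, row.names = NULL)
}

.woolfCI <- function(cells, level = 0.95) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  lor <- log((cells[1] * cells[4]) / (cells[2] * cells[3]))
  se <- sqrt(sum(1 / cells))
  exp(lor + c(-1, 1) * z * se)
}

#' Intra- vs inter-modular co-targeting association
#'
#' Tests whether a module contains more intra-modular (both endpoints in
#' the module) than inter-modular (one endpoint in the module) significant
#' co-targeting relationships than expected. With `x` analysis units in the
#' module and `y` in the remaining modules, the possible intra-modular
#' pairs are `M = x(x-1)/2` and the possible inter-modular pairs
#' `N = x * y`; observed significant counts `m` and `n` fill the 2x2 table
#' `[[m, M-m], [n, N-n]]`, tested two-sided with Fisher's exact test. The
#' odds ratio uses the Haldane correction when a zero cell occurs, with a
#' Woolf log-OR 95% confidence interval.
#'
#' @param network a [CoTargetNetwork-class].
#' @param assignment named character vector mapping analysis units to
#'   module labels. Units are miRNA families by default; set
#'   `unit = "mirna"` to count individual miRNAs (family degree structure
#'   expanded to members).
#' @param module_label the module of interest.
#' @param unit `"family"` (default) or `"mirna"`.
#' @param conf_level confidence level of the Woolf interval (default 0.95).
#' @return list with `x`, `y`, `m`, `M`, `n`, `N`, `p` (two-sided Fisher),
#'   `or` (Haldane-corrected when needed) and `ci` (length-2 vector).
#' @export
intraInterTest <- function(network, assignment, module_label,
                           unit = c("family", "mirna"), conf_level = 0.95) {
  stopifnot(is(network, "CoTargetNetwork"))
  unit <- match.arg(unit)
  fams <- network@nodes$family_id
  if (unit == "family") {
    units_mod <- assignment[fams]
    if (anyNA(units_mod))
      stop("network family without module label: ",
           paste(head(fams[is.na(units_mod)], 3), collapse = ", "),
           call. = FALSE)
    x <- sum(units_mod == module_label)
    y <- sum(units_mod != module_label)
    sig <- significantEdges(network)
    in_a <- assignment[sig$family_a] == module_label
    in_b <- assignment[sig$family_b] == module_label
  } else {
    mf <- network@mirna_family
    units_mod <- assignment[names(mf)]
    if (anyNA(units_mod))
      stop("network miRNA without module label", call. = FALSE)
    x <- sum(units_mod == module_label)
    y <- sum(units_mod != module_label)
    # expand each family edge to all member-miRNA pairs
    sig0 <- significantEdges(network)
    members <- split(names(mf), unname(mf))
    in_a <- in_b <- logical(0)
    for (i in seq_len(nrow(sig0))) {
      ma <- members[[sig0$family_a[i]]]; mb <- members[[sig0$family_b[i]]]
      grid <- expand.grid(a = ma, b = mb, stringsAsFactors = FALSE)
      in_a <- c(in_a, assignment[grid$a] == module_label)
      in_b <- c(in_b, assignment[grid$b] == module_label)
    }
  }
  if (x < 2)
    stop("module '", module_label, "' has fewer than 2 analysis units",
         call. = FALSE)
  m <- sum(in_a & in_b)
  n <- sum(xor(in_a, in_b))
  M <- x * (x - 1) / 2
  N <- x * y
  tab <- rbind(c(m, M - m), c(n, N - n))
  p <- fisher.test(tab, alternative = "two.sided")$p.value
  cells <- as.numeric(t(tab))
  if (any(cells == 0)) cells <- cells + 0.5
  or <- (cells[1] * cells[4]) / (cells[2] * cells[3])
  list(x = x, y = y, m = m, M = M, n = n, N = N,
       p = p, or = or, ci = .woolfCI(cells, conf_level))
}
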