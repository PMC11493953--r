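## Reading and validating TargetScan-style target tables, grouping miRNAs
## into seed families, and the inclusion / seed-similarity filters applied
## before co-targeting testing.

.fmtStop <- function(...) stop(sprintf(...), call. = FALSE)

#' Read a tab-separated miRNA target table
#'
#' Expects columns `mirna`, `family`, `seed`, `gene`, `conserved` (header
#' names case-insensitive; `miRNA` accepted). Lines starting with `#`
#' (provenance headers) are skipped. Duplicate (family, gene) rows are
#' collapsed; families are validated (members share one seed, no seed is
#' declared in two families).
#'
#' @param path target table file.
#' @param features optional data.frame of per-gene features (see
#'   [readFeatureTable()]); genes targeted but absent from it are reported.
#' @return a [TargetCatalog-class].
#' @export
readTargetTable <- function(path, features = NULL) {
  if (!file.exists(path)) .fmtStop("target table not found: %s", path)
  tab <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  if (nrow(tab) == 0L) .fmtStop("target table is empty: %s", path)
  names(tab) <- tolower(names(tab))
  names(tab)[names(tab) == "mirna"] <- "mirna"
  need <- c("mirna", "family", "seed", "gene", "conserved")
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols))
    .fmtStop("target table missing column(s): %s",
             paste(missing_cols, collapse = ", "))
  tab$conserved <- as.logical(tab$conserved)

  mirnas <- unique(tab[, c("mirna", "family", "seed")])
  names(mirnas) <- c("mirna_id", "family_id", "seed")
  mirnas <- mirnas[order(mirnas$mirna_id), , drop = FALSE]
  rownames(mirnas) <- NULL
  # a miRNA is conserved if any of its rows is flagged conserved
  cons <- tapply(tab$conserved, tab$mirna, any)
  mirnas$conserved <- unname(cons[mirnas$mirna_id])

  # collapse duplicate (family, gene) rows; a target is conserved if any
  # supporting row is
  key <- paste(tab$family, tab$gene, sep = "\r")
  first <- !duplicated(key)
  cons_target <- tapply(tab$conserved, key, any)
  fg <- tab[first, c("family", "gene")]
  fg$conserved <- unname(cons_target[key[first]])
  fams <- sort(unique(fg$family))
  targets <- lapply(fams, function(f) {
    g <- fg$gene[fg$family == f]
    o <- order(g)
    g[o]
  })
  names(targets) <- fams
  target_conserved <- lapply(fams, function(f) {
    sel <- fg$family == f
    fg$conserved[sel][order(fg$gene[sel])]
  })
  names(target_conserved) <- fams

  feat <- if (is.null(features)) {
    data.frame(gene_id = character(0), utr_length = numeric(0),
               gc = numeric(0), phylop = numeric(0))
  } else features
  if (nrow(feat)) {
    unknown <- setdiff(unique(fg$gene), feat$gene_id)
    if (length(unknown))
      message(length(unknown), " target gene(s) without features, e.g. ",
              paste(head(unknown, 3), collapse = ", "))
  }
  new("TargetCatalog", mirnas = mirnas, targets = targets,
      target_conserved = target_conserved, features = feat)
}

#' Read a tab-separated per-gene 3'UTR feature table
#'
#' Columns `gene`, `utr_length`, `gc`, `phylop` (`gene_id` accepted).
#'
#' @param path feature table file.
#' @return data.frame with columns `gene_id`, `utr_length`, `gc`, `phylop`.
#' @export
readFeatureTable <- function(path) {
  if (!file.exists(path)) .fmtStop("feature table not found: %s", path)
  tab <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  names(tab) <- tolower(names(tab))
  names(tab)[names(tab) == "gene"] <- "gene_id"
  need <- c("gene_id", "utr_length", "gc", "phylop")
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols))
    .fmtStop("feature table missing column(s): %s",
             paste(missing_cols, collapse = ", "))
  tab[, need]
}

#' Apply the family inclusion filters
#'
#' Retains a family iff its target-set size is at least `min_targets`
#' (counting conserved targets only when `conserved_only = TRUE`, in which
#' case non-conserved targets are also dropped from retained families and
#' families whose members are all non-conserved are removed).
#'
#' Idempotent: filtering an already-filtered catalog changes nothing.
#'
#' @param catalog a [TargetCatalog-class].
#' @param min_targets minimum target-set size (default 300).
#' @param conserved_only restrict to conserved miRNAs and conserved targets.
#' @return the filtered [TargetCatalog-class]; removals are reported with
#'   `message()`.
#' @export
filterFamilies <- function(catalog, min_targets = 300, conserved_only = FALSE) {
  stopifnot(is(catalog, "TargetCatalog"))
  if (min_targets < 1) stop("min_targets must be >= 1", call. = FALSE)
  targets <- catalog@targets
  cons <- catalog@target_conserved
  mirnas <- catalog@mirnas
  if (conserved_only) {
    keep_m <- mirnas$conserved
    mirnas <- mirnas[keep_m, , drop = FALSE]
    targets <- lapply(names(targets), function(f)
      targets[[f]][cons[[f]]])
    names(targets) <- names(cons)
    cons <- lapply(cons, function(x) x[x])
    targets <- targets[names(targets) %in% mirnas$family_id]
    cons <- cons[names(targets)]
  }
  sizes <- lengths(targets)
  keep <- names(targets)[sizes >= min_targets]
  dropped <- setdiff(names(catalog@targets), keep)
  if (length(dropped))
    message("filterFamilies: removed ", length(dropped), " of ",
            length(catalog@targets), " families (min_targets = ",
            min_targets, if (conserved_only) ", conserved only" else "", ")")
  new("TargetCatalog",
      mirnas = mirnas[mirnas$family_id %in% keep, , drop = FALSE],
      targets = targets[keep],
      target_conserved = cons[keep],
      features = catalog@features)
}

#' Hamming distance between two seeds
#'
#' Number of mismatching positions between two equal-length sequences.
#'
#' @param seed_a,seed_b character scalars of equal length.
#' @return non-negative integer.
#' @examples
#' seedHamming("GAGGUAG", "GAGGUAC")  # 1
#' @export
seedHamming <- function(seed_a, seed_b) {
  stopifnot(is.character(seed_a), is.character(seed_b),
            length(seed_a) == 1L, length(seed_b) == 1L)
  if (nchar(seed_a) != nchar(seed_b))
    stop("seeds must have equal length", call. = FALSE)
  sum(strsplit(seed_a, "")[[1]] != strsplit(seed_b, "")[[1]])
}

#' Family pairs excluded a priori for seed similarity
#'
#' All unordered family pairs whose seeds are identical up to
#' `max_mismatch` substitutions (Hamming distance at aligned positions;
#' no shifts) are excluded from the co-targeting statistics, since their
#' shared targets are explained by the seed itself.
#'
#' @param catalog a [TargetCatalog-class].
#' @param max_mismatch maximum seed Hamming distance to exclude (default 1).
#' @return data.frame with columns `family_a`, `family_b` (lexicographically
#'   ordered within and across rows) and `distance`.
#' @export
excludedPairs <- function(catalog, max_mismatch = 1) {
  stopifnot(is(catalog, "TargetCatalog"))
  fam_seed <- unique(catalog@mirnas[, c("family_id", "seed")])
  fam_seed <- fam_seed[order(fam_seed$family_id), , drop = FALSE]
  n <- nrow(fam_seed)
  out <- data.frame(family_a = character(0), family_b = character(0),
                    distance = integer(0), stringsAsFactors = FALSE)
  if (n < 2) return(out)
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      d <- seedHamming(fam_seed$seed[i], fam_seed$seed[j])
      if (d <= max_mismatch) {
        out <- rbind(out, data.frame(
          family_a = fam_seed$family_id[i], family_b = fam_seed$family_id[j],
          distance = d, stringsAsFactors = FALSE))
      }
    }
  }
  rownames(out) <- NULL
  out
}
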