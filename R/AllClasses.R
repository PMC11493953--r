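#' @import methods
#' @importFrom stats cor cor.test p.adjust rbinom rlnorm rnbinom rpois rnorm
#'   rbeta runif sd wilcox.test fisher.test r2dtable setNames quantile median
#' @importFrom utils read.delim write.table packageVersion head
NULL

.SEED_ALPHABET <- c("A", "U", "C", "G")
.SEED_LENGTH <- 7L

#' TargetCatalog: miRNA families and their target-gene sets
#'
#' Container for a TargetScan-style target catalog: one row per miRNA
#' (id, seed, family, conservation flag), one target-gene set per family,
#' and per-gene 3'UTR features used for control matching.
#'
#' miRNAs sharing a seed have identical predicted target sets and are
#' grouped into one family, the unit of all downstream statistics.
#'
#' @slot mirnas data.frame with columns `mirna_id`, `family_id`, `seed`,
#'   `conserved` (one row per miRNA).
#' @slot targets named list, `family_id` -> character vector of target gene
#'   ids. For each (family, gene) pair an optional `conserved` flag is kept
#'   in the `target_conserved` attribute-free companion list.
#' @slot target_conserved named list, `family_id` -> logical vector parallel
#'   to `targets[[family_id]]` (interaction-level conservation).
#' @slot features data.frame with columns `gene_id`, `utr_length`, `gc`,
#'   `phylop` (may be empty if features are supplied separately).
#'
#' @seealso [readTargetTable()], [filterFamilies()], [excludedPairs()]
#' @export
setClass("TargetCatalog",
  slots = c(
    mirnas = "data.frame",
    targets = "list",
    target_conserved = "list",
    features = "data.frame"
  )
)

setValidity("TargetCatalog", function(object) {
  m <- object@mirnas
  msgs <- character(0)
  need <- c("mirna_id", "family_id", "seed", "conserved")
  if (!all(need %in% names(m))) {
    return(paste("mirnas must have columns:", paste(need, collapse = ", ")))
  }
  if (anyDuplicated(m$mirna_id)) {
    msgs <- c(msgs, "duplicated mirna_id: each miRNA belongs to exactly one family")
  }
  bad <- nchar(m$seed) != .SEED_LENGTH |
    grepl(paste0("[^", paste(.SEED_ALPHABET, collapse = ""), "]"), m$seed)
  if (any(bad)) {
    msgs <- c(msgs, sprintf("invalid seed (must be 7-nt over A/U/C/G): %s",
                            paste(unique(m$mirna_id[bad]), collapse = ", ")))
  }
  seed_per_fam <- tapply(m$seed, m$family_id, function(s) length(unique(s)))
  if (any(seed_per_fam > 1)) {
    msgs <- c(msgs, sprintf("family with discordant member seeds: %s",
                            paste(names(seed_per_fam)[seed_per_fam > 1], collapse = ", ")))
  }
  fam_seed <- unique(m[, c("family_id", "seed")])
  if (anyDuplicated(fam_seed$seed)) {
    dup <- fam_seed$seed[duplicated(fam_seed$seed)]
    msgs <- c(msgs, sprintf(
      "identical seed declared in different families (%s): merge them upstream",
      paste(unique(dup), collapse = ", ")))
  }
  if (!all(names(object@targets) %in% m$family_id)) {
    msgs <- c(msgs, "targets list keyed by unknown family_id")
  }
  if (length(object@target_conserved) &&
      !identical(lengths(object@target_conserved)[names(object@targets)],
                 lengths(object@targets))) {
    msgs <- c(msgs, "target_conserved must parallel targets")
  }
  f <- object@features
  if (nrow(f)) {
    needf <- c("gene_id", "utr_length", "gc", "phylop")
    if (!all(needf %in% names(f))) {
      msgs <- c(msgs, paste("features must have columns:", paste(needf, collapse = ", ")))
    } else {
      if (any(f$utr_length <= 0)) msgs <- c(msgs, "utr_length must be > 0")
      if (any(f$gc <= 0 | f$gc >= 1)) msgs <- c(msgs, "gc must lie in (0,1)")
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' ControlSet: matched control genes for one miRNA family
#'
#' Case-control pairing of each target gene with a control gene of similar
#' 3'UTR length, GC content and phyloP score (or `NA` when no candidate
#' survived the matching windows).
#'
#' @slot family_id scalar character.
#' @slot pairs data.frame with columns `target_gene`, `control_gene`
#'   (`NA_character_` marks an absent control).
#'
#' @seealso [buildControlSet()], [validateMatching()]
#' @export
setClass("ControlSet",
  slots = c(family_id = "character", pairs = "data.frame")
)

setValidity("ControlSet", function(object) {
  if (length(object@family_id) != 1L) return("family_id must be scalar")
  p <- object@pairs
  if (!all(c("target_gene", "control_gene") %in% names(p))) {
    return("pairs must have columns target_gene, control_gene")
  }
  if (anyDuplicated(p$target_gene)) return("duplicated target_gene in pairs")
  TRUE
})

#' CoTargetNetwork: tested family pairs and the significant co-targeting graph
#'
#' Result of [detectPairs()]: every tested (non-excluded) unordered family
#' pair with its two directional 2x2 tables summarised as p/q-values and
#' odds ratios, the bidirectional significance call, and per-family node
#' summaries (degree over significant edges).
#'
#' @slot edges data.frame, one row per tested pair: `family_a`, `family_b`,
#'   `n_shared`, `p_ab`, `p_ba`, `q_ab`, `q_ba`, `or_ab`, `or_ba`,
#'   `or_combined`, `significant`.
#' @slot nodes data.frame, one row per family: `family_id`, `n_members`,
#'   `degree`.
#' @slot mirna_family named character vector mapping miRNA id -> family id
#'   (used to broadcast family degrees to individual miRNAs).
#' @slot alpha numeric significance level applied to both adjusted
#'   directional p-values.
#' @slot seed integer seed recorded for provenance (NA when not applicable).
#'
#' @export
setClass("CoTargetNetwork",
  slots = c(
    edges = "data.frame",
    nodes = "data.frame",
    mirna_family = "character",
    alpha = "numeric",
    seed = "integer"
  )
)

setValidity("CoTargetNetwork", function(object) {
  e <- object@edges
  need <- c("family_a", "family_b", "n_shared", "p_ab", "p_ba", "q_ab",
            "q_ba", "or_ab", "or_ba", "or_combined", "significant")
  if (nrow(e) && !all(need %in% names(e))) {
    return(paste("edges must have columns:", paste(need, collapse = ", ")))
  }
  if (!all(c("family_id", "n_members", "degree") %in% names(object@nodes))) {
    return("nodes must have columns family_id, n_members, degree")
  }
  if (length(object@alpha) != 1L || object@alpha <= 0 || object@alpha > 1) {
    return("alpha must be a probability in (0, 1]")
  }
  # degree must equal the number of incident significant edges
  sig <- e[e$significant, , drop = FALSE]
  deg <- table(factor(c(sig$family_a, sig$family_b),
                      levels = object@nodes$family_id))
  if (!all(object@nodes$degree == as.integer(deg))) {
    return("node degrees inconsistent with significant edges")
  }
  TRUE
})

#' StudyBundle: a complete (synthetic) co-targeting study
#'
#' Extends `SummarizedExperiment` (counts assay: miRNA x sample, colData:
#' stage/sex/replicate/lib_size) with the target catalog, module assignments
#' and, for synthetic studies, the planted ground truth.
#'
#' @slot catalog [TargetCatalog-class] for the profiled miRNAs.
#' @slot moduleAssignments named character vector, miRNA id -> module label.
#' @slot truth list with elements `planted_pairs` (data.frame `family_a`,
#'   `family_b`, `kappa`, `n_shared`, `expected_shared`) and
#'   `module_profiles` (matrix module x stage of mean multipliers); empty
#'   list for non-synthetic studies.
#'
#' @seealso [generateStudy()], [writeStudyBundle()], [readStudyBundle()]
#' @export
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
setClass("StudyBundle",
  contains = "SummarizedExperiment",
  slots = c(
    catalog = "TargetCatalog",
    moduleAssignments = "character",
    truth = "list"
  )
)

setValidity("StudyBundle", function(object) {
  msgs <- character(0)
  ids <- rownames(object)
  if (!all(ids %in% object@catalog@mirnas$mirna_id)) {
    msgs <- c(msgs, "every profiled miRNA must appear in the catalog")
  }
  if (!all(ids %in% names(object@moduleAssignments))) {
    msgs <- c(msgs, "every profiled miRNA must have a module assignment")
  }
  feat <- object@catalog@features
  if (nrow(feat)) {
    tg <- unique(unlist(object@catalog@targets, use.names = FALSE))
    if (!all(tg %in% feat$gene_id)) {
      msgs <- c(msgs, "every target gene must have features")
    }
  }
  if (length(msgs)) msgs else TRUE
})
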