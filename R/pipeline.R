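## Pipeline plumbing: tab-separated readers/writers with provenance
## headers, StudyBundle (de)serialization, and the subcommand entry points
## used by the inst/scripts/cotargetnet dispatcher.

.configHash <- function(config) {
  sprintf("%08x", .hashString(yaml::as.yaml(unclass(config))))
}

.provenance <- function(seed = NA, config = NULL) {
  sprintf("# CoTargetNet v%s | config_hash=%s | seed=%s",
          as.character(packageVersion("CoTargetNet")),
          if (is.null(config)) "none" else .configHash(config),
          if (is.na(seed)) "none" else as.integer(seed))
}

.writeTSV <- function(df, path, seed = NA, config = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(.provenance(seed, config), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.logMsg <- function(verbose, ...) if (verbose) message(...)

#' Write a StudyBundle to tab-separated files
#'
#' Writes seven files into `dir`: `counts.tsv`, `sample_metadata.tsv`,
#' `target_table.tsv`, `gene_features.tsv`, `module_assignments.tsv`,
#' `truth.tsv` and `config.yaml`. Every table begins with a provenance
#' comment line and is otherwise strictly tab-separated with a header row.
#'
#' @param bundle a [StudyBundle-class].
#' @param dir output directory (created if needed).
#' @return invisibly, the vector of file paths.
#' @export
writeStudyBundle <- function(bundle, dir) {
  stopifnot(is(bundle, "StudyBundle"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- bundle@truth$config
  seed <- bundle@truth$seed
  if (is.null(seed)) seed <- NA

  counts <- SummarizedExperiment::assay(bundle, "counts")
  cdf <- data.frame(mirna_id = rownames(counts), counts, check.names = FALSE,
                    stringsAsFactors = FALSE)
  meta <- as.data.frame(SummarizedExperiment::colData(bundle))
  meta <- data.frame(sample_id = rownames(meta), meta,
                     stringsAsFactors = FALSE, row.names = NULL)
  cat_obj <- bundle@catalog
  m <- cat_obj@mirnas
  tt <- do.call(rbind, lapply(names(cat_obj@targets), function(f) {
    mem <- m[m$family_id == f, , drop = FALSE]
    genes <- cat_obj@targets[[f]]
    cons <- cat_obj@target_conserved[[f]]
    do.call(rbind, lapply(seq_len(nrow(mem)), function(i)
      data.frame(mirna = mem$mirna_id[i], family = f, seed = mem$seed[i],
                 gene = genes, conserved = cons, stringsAsFactors = FALSE)))
  }))
  mods <- data.frame(mirna_id = names(bundle@moduleAssignments),
                     module = unname(bundle@moduleAssignments),
                     stringsAsFactors = FALSE)
  truth <- plantedPairs(bundle)

  paths <- c(
    counts = .writeTSV(cdf, file.path(dir, "counts.tsv"), seed, cfg),
    metadata = .writeTSV(meta, file.path(dir, "sample_metadata.tsv"), seed, cfg),
    targets = .writeTSV(tt, file.path(dir, "target_table.tsv"), seed, cfg),
    features = .writeTSV(cat_obj@features, file.path(dir, "gene_features.tsv"),
                         seed, cfg),
    modules = .writeTSV(mods, file.path(dir, "module_assignments.tsv"),
                        seed, cfg),
    truth = .writeTSV(truth, file.path(dir, "truth.tsv"), seed, cfg)
  )
  cfg_path <- file.path(dir, "config.yaml")
  if (!is.null(cfg)) {
    writeLines(yaml::as.yaml(unclass(cfg)), cfg_path)
    paths <- c(paths, config = cfg_path)
  }
  invisible(paths)
}

#' Read a StudyBundle from a directory written by [writeStudyBundle()]
#'
#' @param dir directory containing the bundle files.
#' @return a [StudyBundle-class].
#' @export
readStudyBundle <- function(dir) {
  features <- readFeatureTable(file.path(dir, "gene_features.tsv"))
  cat_obj <- readTargetTable(file.path(dir, "target_table.tsv"), features)
  cdf <- read.delim(file.path(dir, "counts.tsv"), comment.char = "#",
                    check.names = FALSE, stringsAsFactors = FALSE)
  counts <- as.matrix(cdf[, -1, drop = FALSE])
  rownames(counts) <- cdf$mirna_id
  storage.mode(counts) <- "integer"
  meta <- read.delim(file.path(dir, "sample_metadata.tsv"), comment.char = "#",
                     stringsAsFactors = FALSE)
  mods <- read.delim(file.path(dir, "module_assignments.tsv"),
                     comment.char = "#", stringsAsFactors = FALSE)
  truth <- read.delim(file.path(dir, "truth.tsv"), comment.char = "#",
                      stringsAsFactors = FALSE)
  cfg_path <- file.path(dir, "config.yaml")
  cfg <- NULL; seed <- NA_integer_
  if (file.exists(cfg_path)) {
    raw <- yaml::read_yaml(cfg_path)
    raw <- lapply(raw, function(x) if (is.list(x)) unlist(x) else x)
    cfg <- do.call(simConfig, raw)
    seed <- cfg$rng_seed
  }
  minfo <- cat_obj@mirnas
  ridx <- match(rownames(counts), minfo$mirna_id)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts),
    colData = S4Vectors::DataFrame(meta[, -1, drop = FALSE],
                                   row.names = meta$sample_id),
    rowData = S4Vectors::DataFrame(
      family_id = minfo$family_id[ridx],
      seed = minfo$seed[ridx],
      module = mods$module[match(rownames(counts), mods$mirna_id)],
      row.names = rownames(counts)))
  new("StudyBundle", se, catalog = cat_obj,
      moduleAssignments = setNames(mods$module, mods$mirna_id),
      truth = list(planted_pairs = truth,
                   module_profiles = NULL, config = cfg, seed = seed))
}

#' Simulate subcommand: generate and write a synthetic study
#'
#' @param config a [simConfig()] (or path to a YAML file of its fields).
#' @param out_dir output directory.
#' @param verbose print a summary (default TRUE).
#' @return invisibly, the written file paths.
#' @export
runSimulate <- function(config = simConfig(), out_dir, verbose = TRUE) {
  if (is.character(config)) {
    raw <- yaml::read_yaml(config)
    raw <- lapply(raw, function(x) if (is.list(x)) unlist(x) else x)
    config <- do.call(simConfig, raw)
  }
  bundle <- generateStudy(config)
  paths <- writeStudyBundle(bundle, out_dir)
  .logMsg(verbose, sprintf(
    "simulate: %d miRNAs / %d families, %d genes, %d samples, %d planted pair(s) -> %s",
    nrow(bundle), length(catalog(bundle)@targets), config$n_genes,
    ncol(bundle), nrow(plantedPairs(bundle)), out_dir))
  invisible(paths)
}

#' Co-targeting subcommand: end-to-end pair detection
#'
#' Runs the full chain — family inclusion filter, seed-similarity
#' exclusion, matched-control construction, bidirectional testing — on a
#' target table + feature table and writes the edge list, node summaries
#' and a key-value summary report.
#'
#' @param target_table path to the tab-separated target table.
#' @param feature_table path to the tab-separated gene feature table.
#' @param out_dir output directory.
#' @param alpha significance level (default 0.05).
#' @param min_targets family inclusion threshold (default 300).
#' @param conserved_only restrict to conserved targets (default FALSE).
#' @param max_mismatch seed-similarity exclusion distance (default 1).
#' @param seed integer RNG seed for control matching.
#' @param dry_run validate inputs and report stage counts without writing.
#' @param verbose log stage counts to standard error (default TRUE).
#' @return invisibly, the [CoTargetNetwork-class].
#' @export
runCotarget <- function(target_table, feature_table, out_dir,
                        alpha = 0.05, min_targets = 300,
                        conserved_only = FALSE, max_mismatch = 1,
                        seed = 1L, dry_run = FALSE, verbose = TRUE) {
  features <- readFeatureTable(feature_table)
  cat_obj <- readTargetTable(target_table, features)
  cat_obj@features <- features
  .logMsg(verbose, "cotarget: ", length(cat_obj@targets), " families in")
  filtered <- suppressMessages(
    filterFamilies(cat_obj, min_targets = min_targets,
                   conserved_only = conserved_only))
  .logMsg(verbose, "cotarget: ", length(filtered@targets),
          " families after filters (min_targets = ", min_targets, ")")
  excl <- excludedPairs(filtered, max_mismatch = max_mismatch)
  .logMsg(verbose, "cotarget: ", nrow(excl),
          " pair(s) excluded for seed similarity")
  if (dry_run) {
    .logMsg(verbose, "cotarget: dry run, no output written")
    return(invisible(NULL))
  }
  controls <- buildControlSets(filtered, matchingConfig(rng_seed = seed))
  network <- detectPairs(filtered, controls, excl, alpha = alpha,
                         seed = seed)
  .logMsg(verbose, "cotarget: ", nrow(network@edges), " pairs tested, ",
          sum(network@edges$significant), " significant at alpha = ", alpha)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  .writeTSV(network@edges, file.path(out_dir, "edges.tsv"), seed)
  .writeTSV(network@nodes, file.path(out_dir, "nodes.tsv"), seed)
  summary_lines <- c(
    .provenance(seed),
    paste0("families_in\t", length(cat_obj@targets)),
    paste0("families_after_filters\t", length(filtered@targets)),
    paste0("pairs_excluded_by_seed\t", nrow(excl)),
    paste0("pairs_tested\t", nrow(network@edges)),
    paste0("pairs_significant\t", sum(network@edges$significant)),
    paste0("alpha\t", alpha))
  writeLines(summary_lines, file.path(out_dir, "summary.txt"))
  invisible(network)
}

#' Module-stats subcommand: eigengenes, trait correlations, memberships
#'
#' Computes log2(CPM + 1), then per module the eigengene, its Pearson
#' correlation with the stage code, and per-miRNA module membership and
#' trait significance.
#'
#' @param bundle a [StudyBundle-class] or a directory readable by
#'   [readStudyBundle()].
#' @param out_dir optional output directory; when given, writes
#'   `module_summary.tsv` and `mirna_module_stats.tsv`.
#' @param min_module_size modules with fewer miRNAs are skipped (default 2).
#' @return invisibly, a list with `summary` and `per_mirna` data.frames.
#' @export
runModuleStats <- function(bundle, out_dir = NULL, min_module_size = 2L) {
  if (is.character(bundle)) bundle <- readStudyBundle(bundle)
  stopifnot(is(bundle, "StudyBundle"))
  counts <- SummarizedExperiment::assay(bundle, "counts")
  logcpm <- log2(cpm(counts) + 1)
  trait <- stageCodes(SummarizedExperiment::colData(bundle)$stage)
  mods <- moduleAssignments(bundle)
  summary_rows <- list(); per_mirna <- list()
  for (mod in sort(unique(mods))) {
    ids <- names(mods)[mods == mod]
    ids <- intersect(ids, rownames(logcpm))
    if (length(ids) < min_module_size) next
    sub <- logcpm[ids, , drop = FALSE]
    sub <- sub[apply(sub, 1, sd) > 0, , drop = FALSE]
    if (nrow(sub) < min_module_size) next
    me <- moduleEigengene(sub)
    tc <- moduleTraitCorrelation(me$eigengene, trait)
    summary_rows[[mod]] <- data.frame(
      module = mod, n_mirnas = nrow(sub),
      variance_explained = me$variance_explained,
      trait_r = tc$r, trait_p = tc$p, stringsAsFactors = FALSE)
    ms <- membershipAndSignificance(sub, me$eigengene, trait)
    ms$module <- mod
    per_mirna[[mod]] <- ms
  }
  out <- list(summary = do.call(rbind, c(summary_rows,
                                         list(make.row.names = FALSE))),
              per_mirna = do.call(rbind, c(per_mirna,
                                           list(make.row.names = FALSE))))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    .writeTSV(out$summary, file.path(out_dir, "module_summary.tsv"))
    .writeTSV(out$per_mirna, file.path(out_dir, "mirna_module_stats.tsv"))
  }
  invisible(out)
}

#' Enrichment subcommand: DE-target distribution comparison
#'
#' @param de_table path to a tab-separated DE table (columns `id`,
#'   `log2fc`, `padj`) or a data.frame.
#' @param target_genes character vector of target genes, or path to a file
#'   with one gene id per line.
#' @param out_dir optional output directory for `enrichment.tsv`.
#' @param ... passed to [targetDEEnrichment()].
#' @return invisibly, the enrichment result list.
#' @export
runEnrich <- function(de_table, target_genes, out_dir = NULL, ...) {
  if (is.character(de_table)) {
    de_table <- read.delim(de_table, comment.char = "#",
                           stringsAsFactors = FALSE)
  }
  if (length(target_genes) == 1L && file.exists(target_genes)) {
    target_genes <- readLines(target_genes)
    target_genes <- target_genes[!grepl("^#", target_genes) &
                                 nzchar(target_genes)]
  }
  de <- classifyDE(de_table)
  res <- targetDEEnrichment(de, target_genes, ...)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    rep <- data.frame(group = rownames(res$table), res$table,
                      stringsAsFactors = FALSE, row.names = NULL)
    .writeTSV(rep, file.path(out_dir, "enrichment.tsv"))
    writeLines(c(.provenance(),
                 paste0("p\t", res$p), paste0("method\t", res$method),
                 paste0("or_up\t", res$column_or[["up"]]),
                 paste0("or_down\t", res$column_or[["down"]]),
                 paste0("or_ns\t", res$column_or[["ns"]])),
               file.path(out_dir, "enrichment_summary.txt"))
  }
  invisible(res)
}

#' Summarize subcommand: overlap of two id sets
#'
#' @param set_a,set_b character vectors of ids, or paths to files with one
#'   id per line.
#' @param out_file optional path for the tab-separated summary.
#' @return invisibly, the [summarizeDEOverlap()] list.
#' @export
runSummarize <- function(set_a, set_b, out_file = NULL) {
  readSet <- function(x) {
    if (length(x) == 1L && file.exists(x)) {
      x <- readLines(x)
      x <- x[!grepl("^#", x) & nzchar(x)]
    }
    x
  }
  res <- summarizeDEOverlap(readSet(set_a), readSet(set_b))
  if (!is.null(out_file)) {
    .writeTSV(data.frame(res), out_file)
  }
  invisible(res)
}
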