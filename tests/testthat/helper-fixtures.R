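# Fixtures and independent oracles shared across the suite.

# deterministic set of seeds at pairwise Hamming distance >= 2
.FIXED_SEEDS <- c("AAAAAAA", "UUUUUUU", "CCCCCCC", "GGGGGGG",
                  "AAUUCCG", "UUGGAAC", "CCAAGGU", "GGUUCCA",
                  "AUCGAUC", "UAGCUAG", "CGAUCGA", "GCUAGCU")

# build a TargetCatalog from a named list of target-gene sets; one miRNA per
# family unless members is given
makeCatalog <- function(targets, features = NULL, seeds = NULL,
                        members = NULL) {
  fams <- names(targets)
  if (is.null(seeds)) seeds <- .FIXED_SEEDS[seq_along(fams)]
  if (is.null(members)) members <- rep(1L, length(fams))
  mirnas <- data.frame(
    mirna_id = unlist(lapply(seq_along(fams), function(i)
      sprintf("%s-m%d", fams[i], seq_len(members[i])))),
    family_id = rep(fams, members),
    seed = rep(seeds, members),
    conserved = TRUE, stringsAsFactors = FALSE)
  if (is.null(features)) {
    features <- data.frame(gene_id = character(0), utr_length = numeric(0),
                           gc = numeric(0), phylop = numeric(0))
  }
  new("TargetCatalog", mirnas = mirnas,
      targets = lapply(targets, function(x) sort(unique(x))),
      target_conserved = lapply(targets,
                                function(x) rep(TRUE, length(unique(x)))),
      features = features)
}

makeFeatures <- function(n, seed = 1) {
  set.seed(seed)
  data.frame(gene_id = sprintf("g%04d", seq_len(n)),
             utr_length = rlnorm(n, 7, 0.6),
             gc = rbeta(n, 40, 45),
             phylop = rnorm(n, 1, 0.3),
             stringsAsFactors = FALSE)
}

# assemble a CoTargetNetwork by hand from an edge list with significance
# flags; degrees derived from the significant edges
makeNetwork <- function(edges, families, n_members = NULL, alpha = 0.05) {
  if (is.null(n_members)) n_members <- rep(1L, length(families))
  if (nrow(edges)) {
    for (col in c("n_shared")) if (is.null(edges[[col]])) edges[[col]] <- 0L
    for (col in c("p_ab", "p_ba", "q_ab", "q_ba"))
      if (is.null(edges[[col]])) edges[[col]] <- 0.01
    for (col in c("or_ab", "or_ba"))
      if (is.null(edges[[col]])) edges[[col]] <- 2
    if (is.null(edges$or_combined))
      edges$or_combined <- sqrt(edges$or_ab * edges$or_ba)
  } else {
    edges <- data.frame(family_a = character(0), family_b = character(0),
                        n_shared = integer(0), p_ab = numeric(0),
                        p_ba = numeric(0), q_ab = numeric(0),
                        q_ba = numeric(0), or_ab = numeric(0),
                        or_ba = numeric(0), or_combined = numeric(0),
                        significant = logical(0))
  }
  sig <- edges[edges$significant, , drop = FALSE]
  deg <- table(factor(c(sig$family_a, sig$family_b), levels = families))
  nodes <- data.frame(family_id = families,
                      n_members = as.integer(n_members),
                      degree = as.integer(deg), stringsAsFactors = FALSE)
  mirna_family <- setNames(rep(families, n_members),
                           unlist(lapply(seq_along(families), function(i)
                             sprintf("%s-m%d", families[i],
                                     seq_len(n_members[i])))))
  new("CoTargetNetwork", edges = edges, nodes = nodes,
      mirna_family = mirna_family, alpha = alpha, seed = NA_integer_)
}

# Independent oracle for the one-sided exact test: enumerate every table
# with the observed margins using Fisher's factorial form
# P = r1! r2! c1! c2! / (N! a! b! c! d!), summing tables with overlap >= a.
bruteFisherGreater <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c; c2 <- b + d; N <- a + b + c + d
  lp_margin <- lfactorial(r1) + lfactorial(r2) + lfactorial(c1) +
    lfactorial(c2) - lfactorial(N)
  # overlap cell in this parameterization is the top-left entry
  xs <- max(0, r1 - c2):min(r1, c1)
  xs <- xs[xs >= a]
  total <- sum(exp(lp_margin - lfactorial(xs) - lfactorial(r1 - xs) -
                     lfactorial(c1 - xs) - lfactorial(c2 - r1 + xs)))
  min(1, total)
}

# Independent oracle for the two-sided 2x2 exact test (sum of tables no
# more probable than the observed one)
bruteFisherTwoSided <- function(m, Mm, n, Nn) {
  r1 <- m + Mm; r2 <- n + Nn; c1 <- m + n; c2 <- Mm + Nn; N <- r1 + r2
  lp <- function(x) {
    lfactorial(r1) + lfactorial(r2) + lfactorial(c1) + lfactorial(c2) -
      lfactorial(N) - lfactorial(x) - lfactorial(r1 - x) -
      lfactorial(c1 - x) - lfactorial(c2 - r1 + x)
  }
  xs <- max(0, r1 - c2):min(r1, c1)
  lps <- vapply(xs, lp, numeric(1))
  obs <- lp(m)
  min(1, sum(exp(lps[lps <= obs + 1e-7])))
}

# do all non-absent control pairs satisfy the three multiplicative windows?
windowsSatisfied <- function(control_set, features,
                             config = matchingConfig()) {
  pairs <- controlPairs(control_set)
  pairs <- pairs[!is.na(pairs$control_gene), , drop = FALSE]
  if (!nrow(pairs)) return(TRUE)
  ti <- match(pairs$target_gene, features$gene_id)
  ci <- match(pairs$control_gene, features$gene_id)
  ok <- TRUE
  for (spec in list(c("utr_length", "utr_window"), c("gc", "gc_window"),
                    c("phylop", "phylop_window"))) {
    t <- features[[spec[1]]][ti]; v <- features[[spec[1]]][ci]
    w <- config[[spec[2]]]
    lo <- pmin(w[1] * t, w[2] * t); hi <- pmax(w[1] * t, w[2] * t)
    ok <- ok && all(v >= lo & v <= hi)
  }
  ok
}

# planted-pair recovery rates of a detected network against ground truth
recoveryRates <- function(network, truth) {
  sig <- significantEdges(network)
  skey <- paste(pmin(sig$family_a, sig$family_b),
                pmax(sig$family_a, sig$family_b))
  tkey <- paste(pmin(truth$family_a, truth$family_b),
                pmax(truth$family_a, truth$family_b))
  list(sensitivity = if (length(tkey)) mean(tkey %in% skey) else NA_real_,
       precision = if (length(skey)) mean(skey %in% tkey) else NA_real_,
       n_significant = length(skey))
}

# shared pipeline for simulation-based checks: filter, match, detect
runStudyDetection <- function(config, alpha = 0.05) {
  bundle <- generateStudy(config)
  filtered <- suppressMessages(filterFamilies(catalog(bundle), 300))
  controls <- buildControlSets(filtered,
                               matchingConfig(rng_seed = config$rng_seed))
  network <- detectPairs(filtered, controls, excludedPairs(filtered),
                         alpha = alpha, seed = config$rng_seed)
  list(bundle = bundle, network = network)
}
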