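#' @rdname TargetCatalog-class
#' @param x,object a [TargetCatalog-class], [ControlSet-class],
#'   [CoTargetNetwork-class] or [StudyBundle-class]
#' @export
setGeneric("targetSets", function(x) standardGeneric("targetSets"))

#' @rdname TargetCatalog-class
#' @export
setGeneric("geneFeatures", function(x) standardGeneric("geneFeatures"))

#' @rdname TargetCatalog-class
#' @export
setGeneric("mirnaInfo", function(x) standardGeneric("mirnaInfo"))

#' @rdname TargetCatalog-class
#' @export
setGeneric("familyIds", function(x) standardGeneric("familyIds"))

#' @rdname ControlSet-class
#' @export
setGeneric("controlPairs", function(x) standardGeneric("controlPairs"))

#' @rdname ControlSet-class
#' @export
setGeneric("controlGenes", function(x) standardGeneric("controlGenes"))

#' @rdname CoTargetNetwork-class
#' @export
setGeneric("networkEdges", function(x) standardGeneric("networkEdges"))

#' @rdname CoTargetNetwork-class
#' @export
setGeneric("networkNodes", function(x) standardGeneric("networkNodes"))

#' @rdname CoTargetNetwork-class
#' @export
setGeneric("significantEdges", function(x) standardGeneric("significantEdges"))

#' @rdname StudyBundle-class
#' @export
setGeneric("moduleAssignments", function(x) standardGeneric("moduleAssignments"))

#' @rdname StudyBundle-class
#' @export
setGeneric("plantedPairs", function(x) standardGeneric("plantedPairs"))

#' @rdname StudyBundle-class
#' @export
setGeneric("catalog", function(x) standardGeneric("catalog"))

## ---- TargetCatalog methods ----

#' @rdname TargetCatalog-class
#' @export
setMethod("targetSets", "TargetCatalog", function(x) x@targets)

#' @rdname TargetCatalog-class
#' @export
setMethod("geneFeatures", "TargetCatalog", function(x) x@features)

#' @rdname TargetCatalog-class
#' @export
setMethod("mirnaInfo", "TargetCatalog", function(x) x@mirnas)

#' @rdname TargetCatalog-class
#' @export
setMethod("familyIds", "TargetCatalog", function(x) sort(unique(x@mirnas$family_id)))

#' @rdname TargetCatalog-class
#' @export
setMethod("show", "TargetCatalog", function(object) {
  nt <- lengths(object@targets)
  cat("TargetCatalog:", nrow(object@mirnas), "miRNAs in",
      length(unique(object@mirnas$family_id)), "families\n")
  if (length(nt)) {
    cat("  target-set sizes: median", stats::median(nt),
        sprintf("(range %d-%d)\n", min(nt), max(nt)))
  }
  cat("  gene features:", nrow(object@features), "genes\n")
})

## ---- ControlSet methods ----

#' @rdname ControlSet-class
#' @export
setMethod("controlPairs", "ControlSet", function(x) x@pairs)

#' @rdname ControlSet-class
#' @export
setMethod("controlGenes", "ControlSet", function(x) {
  g <- x@pairs$control_gene
  unique(g[!is.na(g)])
})

#' @rdname ControlSet-class
#' @export
setMethod("show", "ControlSet", function(object) {
  n <- nrow(object@pairs)
  na <- sum(is.na(object@pairs$control_gene))
  cat(sprintf("ControlSet for %s: %d targets, %d matched, %d absent\n",
              object@family_id, n, n - na, na))
})

## ---- CoTargetNetwork methods ----

#' @rdname CoTargetNetwork-class
#' @export
setMethod("networkEdges", "CoTargetNetwork", function(x) x@edges)

#' @rdname CoTargetNetwork-class
#' @export
setMethod("networkNodes", "CoTargetNetwork", function(x) x@nodes)

#' @rdname CoTargetNetwork-class
#' @export
setMethod("significantEdges", "CoTargetNetwork", function(x) {
  x@edges[x@edges$significant, , drop = FALSE]
})

#' @rdname CoTargetNetwork-class
#' @export
setMethod("show", "CoTargetNetwork", function(object) {
  cat(sprintf("CoTargetNetwork: %d families, %d tested pairs, %d significant (alpha = %g)\n",
              nrow(object@nodes), nrow(object@edges),
              sum(object@edges$significant), object@alpha))
  if (nrow(object@nodes)) {
    cat("  mean family degree:",
        round(mean(object@nodes$degree), 2), "\n")
  }
})

## ---- StudyBundle methods ----

#' @rdname StudyBundle-class
#' @export
setMethod("moduleAssignments", "StudyBundle", function(x) x@moduleAssignments)

#' @rdname StudyBundle-class
#' @export
setMethod("plantedPairs", "StudyBundle", function(x) {
  if (is.null(x@truth$planted_pairs)) {
    data.frame(family_a = character(0), family_b = character(0),
               kappa = numeric(0), n_shared = integer(0),
               expected_shared = numeric(0))
  } else {
    x@truth$planted_pairs
  }
})

#' @rdname StudyBundle-class
#' @export
setMethod("catalog", "StudyBundle", function(x) x@catalog)

#' @rdname StudyBundle-class
#' @export
setMethod("show", "StudyBundle", function(object) {
  callNextMethod()
  cat(sprintf("catalog: %d families; modules: %d; planted pairs: %d\n",
              length(object@catalog@targets),
              length(unique(object@moduleAssignments)),
              nrow(plantedPairs(object))))
})
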