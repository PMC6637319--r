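# Generics, accessors, show and subset methods for the core classes.

#' @rdname ReadSet-class
#' @param object,x a `ReadSet`
#' @export
setGeneric("readSequences", function(x) standardGeneric("readSequences"))
#' @rdname ReadSet-class
#' @export
setGeneric("readQualities", function(x) standardGeneric("readQualities"))
#' @rdname ReadSet-class
#' @export
setGeneric("mateNumbers", function(x) standardGeneric("mateNumbers"))
#' @rdname ReadSet-class
#' @export
setGeneric("pairIDs", function(x) standardGeneric("pairIDs"))

#' @rdname ReadSet-class
#' @export
setMethod("readSequences", "ReadSet", function(x) x@sequences)
#' @rdname ReadSet-class
#' @export
setMethod("readQualities", "ReadSet", function(x) x@quality)
#' @rdname ReadSet-class
#' @export
setMethod("mateNumbers", "ReadSet", function(x) x@mate)
#' @rdname ReadSet-class
#' @export
setMethod("pairIDs", "ReadSet", function(x) x@pairId)

#' @rdname ReadSet-class
#' @export
setMethod("length", "ReadSet", function(x) length(x@sequences))

#' @rdname ReadSet-class
#' @param i index (numeric, logical, or read ids)
#' @param j,...,drop ignored
#' @export
setMethod("[", "ReadSet", function(x, i, j, ..., drop = TRUE) {
  if (is.character(i)) i <- match(i, names(x@sequences))
  new("ReadSet",
      sequences = x@sequences[i],
      quality = x@quality[i],
      mate = x@mate[i],
      pairId = x@pairId[i])
})

setMethod("show", "ReadSet", function(object) {
  n <- length(object)
  npair <- sum(object@mate == 1L)
  cat(sprintf("ReadSet with %d reads (%d pairs, %d single)\n",
              n, npair, sum(object@mate == 0L)))
  if (n > 0L)
    cat(sprintf("  read length: %d..%d bp\n",
                min(Biostrings::width(object@sequences)),
                max(Biostrings::width(object@sequences))))
})

#' @rdname ContigSet-class
#' @param object,x a `ContigSet`
#' @export
setGeneric("contigSequences", function(x) standardGeneric("contigSequences"))
#' @rdname ContigSet-class
#' @export
setGeneric("contigIDs", function(x) standardGeneric("contigIDs"))
#' @rdname ContigSet-class
#' @export
setGeneric("contigCoverage", function(x) standardGeneric("contigCoverage"))
#' @rdname ContigSet-class
#' @export
setGeneric("contigOrigin", function(x) standardGeneric("contigOrigin"))
#' @rdname ContigSet-class
#' @export
setGeneric("sourceContigs", function(x) standardGeneric("sourceContigs"))

#' @rdname ContigSet-class
#' @export
setMethod("contigSequences", "ContigSet", function(x) x@sequences)
#' @rdname ContigSet-class
#' @export
setMethod("contigIDs", "ContigSet", function(x) names(x@sequences))
#' @rdname ContigSet-class
#' @export
setMethod("contigCoverage", "ContigSet", function(x) x@coverage)
#' @rdname ContigSet-class
#' @export
setMethod("contigOrigin", "ContigSet", function(x) x@origin)
#' @rdname ContigSet-class
#' @export
setMethod("sourceContigs", "ContigSet", function(x) x@sourceContig)

#' @rdname ContigSet-class
#' @export
setMethod("length", "ContigSet", function(x) length(x@sequences))

#' @rdname ContigSet-class
#' @param i index (numeric, logical, or contig ids)
#' @param j,...,drop ignored
#' @export
setMethod("[", "ContigSet", function(x, i, j, ..., drop = TRUE) {
  if (is.character(i)) i <- match(i, names(x@sequences))
  cov <- x@coverage
  if (nrow(cov) > 0L) cov <- cov[i, , drop = FALSE]
  new("ContigSet",
      sequences = x@sequences[i],
      origin = x@origin[i],
      sourceContig = x@sourceContig[i],
      coverage = cov)
})

setMethod("show", "ContigSet", function(object) {
  n <- length(object)
  cat(sprintf("ContigSet with %d contigs (%s bp total)\n", n,
              format(sum(Biostrings::width(object@sequences)), big.mark = ",")))
  if (n > 0L)
    cat(sprintf("  lengths %d..%d bp; coverage samples: %d\n",
                min(Biostrings::width(object@sequences)),
                max(Biostrings::width(object@sequences)),
                ncol(object@coverage)))
})

#' @rdname ClusterAssignment-class
#' @param object,x a `ClusterAssignment`
#' @export
setGeneric("clusterLabels", function(x) standardGeneric("clusterLabels"))
#' @rdname ClusterAssignment-class
#' @export
setGeneric("clusterK", function(x) standardGeneric("clusterK"))
#' @rdname ClusterAssignment-class
#' @export
setGeneric("responsibilities", function(x) standardGeneric("responsibilities"))

#' @rdname ClusterAssignment-class
#' @export
setMethod("clusterLabels", "ClusterAssignment", function(x) x@clusters)
#' @rdname ClusterAssignment-class
#' @export
setMethod("clusterK", "ClusterAssignment", function(x) x@K)
#' @rdname ClusterAssignment-class
#' @export
setMethod("responsibilities", "ClusterAssignment", function(x) x@responsibilities)

setMethod("show", "ClusterAssignment", function(object) {
  cat(sprintf("ClusterAssignment: %d contigs in K = %d clusters (seed %d)\n",
              length(object@clusters), object@K, object@seed))
  tab <- tabulate(object@clusters, nbins = object@K)
  cat("  cluster sizes:", paste(tab, collapse = " "), "\n")
})

#' @rdname TargetCall-class
#' @param object,x a `TargetCall`
#' @export
setGeneric("targetClusters", function(x) standardGeneric("targetClusters"))
#' @rdname TargetCall-class
#' @export
setGeneric("targetContigs", function(x) standardGeneric("targetContigs"))
#' @rdname TargetCall-class
#' @export
setGeneric("rescuedReads", function(x) standardGeneric("rescuedReads"))
#' @rdname TargetCall-class
#' @export
setGeneric("isNoTarget", function(x) standardGeneric("isNoTarget"))

#' @rdname TargetCall-class
#' @export
setMethod("targetClusters", "TargetCall", function(x) x@targetClusters)
#' @rdname TargetCall-class
#' @export
setMethod("targetContigs", "TargetCall", function(x) x@targetContigs)
#' @rdname TargetCall-class
#' @export
setMethod("rescuedReads", "TargetCall", function(x) x@rescuedReads)
#' @rdname TargetCall-class
#' @export
setMethod("isNoTarget", "TargetCall", function(x) x@noTarget)

setMethod("show", "TargetCall", function(object) {
  if (object@noTarget) {
    cat("TargetCall: NO_TARGET (no cluster passed the marker threshold)\n")
  } else {
    cat(sprintf("TargetCall: clusters {%s}, %d contigs, %d rescued reads\n",
                paste(object@targetClusters, collapse = ", "),
                length(object@targetContigs), length(object@rescuedReads)))
  }
})

setMethod("show", "SpeciesEstimate", function(object) {
  cat(sprintf("SpeciesEstimate: K = %d (%s)\n", object@K, object@method))
})

setMethod("show", "GenomeSpec", function(object) {
  cat(sprintf("GenomeSpec '%s' (%s): %d bp, read proportion %.3f\n",
              object@speciesId, object@role, length(object@sequence),
              object@readProportion))
  if (length(object@planted))
    cat(sprintf("  %d planted features, %d annotated genes\n",
                length(object@planted), length(object@genes)))
})

setMethod("show", "EvaluationReport", function(object) {
  cat("EvaluationReport\n")
  cat(sprintf("  clusters scored: %d; truth target clusters: %d\n",
              nrow(object@purity), nrow(object@concentration)))
  d <- object@dichotomy
  if (length(d))
    cat(sprintf("  sensitivity (contig/read): %.1f%% / %.1f%%; specificity: %.1f%% / %.1f%%\n",
                d[["sensitivity_contig"]], d[["sensitivity_read"]],
                d[["specificity_contig"]], d[["specificity_read"]]))
  v <- object@coverage
  if (length(v))
    cat(sprintf("  base coverage %.1f%%, gene coverage %.1f%%\n",
                v[["base_coverage"]], v[["gene_coverage"]]))
})
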