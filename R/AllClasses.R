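#' Sequencing reads with qualities and pairing
#'
#' `ReadSet` is the pipeline's currency: a set of sequencing reads with
#' per-base phred qualities, mate annotation and pair identifiers. Mates of
#' a pair are stored interleaved (mate 1 immediately followed by mate 2).
#'
#' @slot sequences [Biostrings::DNAStringSet] of read sequences; names are
#'   the read identifiers (unique).
#' @slot quality [Biostrings::PhredQuality] per-base qualities (phred+33),
#'   widths identical to `sequences`.
#' @slot mate integer vector: 0 for single reads, 1/2 for the mates of a
#'   pair.
#' @slot pairId character vector, identical for the two mates of a pair and
#'   equal to the read id for single reads.
#'
#' @seealso [readFastq()], [trimReads()], [simulateReads()]
#' @export
setClass("ReadSet", representation(
  sequences = "DNAStringSet",
  quality = "PhredQuality",
  mate = "integer",
  pairId = "character"
))

setValidity("ReadSet", function(object) {
  n <- length(object@sequences)
  if (length(object@quality) != n || length(object@mate) != n ||
      length(object@pairId) != n)
    return("slot lengths differ")
  if (n == 0L) return(TRUE)
  if (is.null(names(object@sequences)) || anyDuplicated(names(object@sequences)))
    return("read ids must be present and unique")
  if (any(Biostrings::width(object@sequences) != Biostrings::width(object@quality)))
    return("sequence and quality widths differ")
  if (!all(object@mate %in% 0:2))
    return("mate must be 0 (single), 1 or 2")
  paired <- object@mate != 0L
  if (any(paired)) {
    # a mate may appear without its partner (e.g. after subsetting), but a
    # pair id can never be shared by more than two reads or by two copies
    # of the same mate
    key <- paste0(object@pairId[paired], "/", object@mate[paired])
    if (anyDuplicated(key))
      return("duplicated (pair id, mate) combination")
  }
  TRUE
})

#' Assembled contigs with per-sample coverage
#'
#' Contigs produced by the built-in unitig assembler or loaded from an
#' external assembler, optionally carrying a per-sample mean-depth matrix
#' filled in by [computeCoverage()].
#'
#' @slot sequences [Biostrings::DNAStringSet]; names are contig ids.
#' @slot origin `"builtin"` or `"external"` per contig.
#' @slot sourceContig id of the pre-fragmentation parent contig (the contig
#'   itself when unfragmented); set by [prepareContigs()].
#' @slot coverage numeric matrix, one row per contig, one column per sample
#'   (0 columns until coverage is computed).
#'
#' @seealso [buildUnitigs()], [prepareContigs()], [computeCoverage()]
#' @export
setClass("ContigSet", representation(
  sequences = "DNAStringSet",
  origin = "character",
  sourceContig = "character",
  coverage = "matrix"
))

setValidity("ContigSet", function(object) {
  n <- length(object@sequences)
  if (length(object@origin) != n || length(object@sourceContig) != n)
    return("slot lengths differ")
  if (n > 0L && (is.null(names(object@sequences)) ||
                 anyDuplicated(names(object@sequences))))
    return("contig ids must be present and unique")
  if (n > 0L && any(Biostrings::width(object@sequences) < 1L))
    return("contigs must have length >= 1")
  if (nrow(object@coverage) != 0L && nrow(object@coverage) != n)
    return("coverage matrix rows must match contig count")
  TRUE
})

#' A synthetic genome used by the community simulator
#'
#' @slot speciesId species identifier.
#' @slot sequence [Biostrings::DNAString] genome sequence.
#' @slot role `"target"` or `"contaminant"`.
#' @slot readProportion fraction of simulated reads drawn from this genome.
#' @slot planted [GenomicRanges::GRanges] of sequences inserted verbatim
#'   (marker genes, rRNA genes), with a `feature_id` metadata column.
#' @slot genes [GenomicRanges::GRanges] gene annotation intervals with a
#'   `gene_id` metadata column.
#' @export
setClass("GenomeSpec", representation(
  speciesId = "character",
  sequence = "DNAString",
  role = "character",
  readProportion = "numeric",
  planted = "GRanges",
  genes = "GRanges"
))

setValidity("GenomeSpec", function(object) {
  if (!object@role %in% c("target", "contaminant"))
    return("role must be 'target' or 'contaminant'")
  if (object@readProportion < 0 || object@readProportion > 1)
    return("readProportion must be in [0, 1]")
  TRUE
})

#' Estimated number of species-level groups
#'
#' The species count used to fix the cluster number K of the binning stage,
#' either estimated from small-subunit rRNA similarity hits or set manually.
#'
#' @slot K positive integer cluster count.
#' @slot hits data.frame of per-taxon assigned read counts (empty for
#'   manual overrides).
#' @slot method `"reference_hits"` or `"manual"`.
#' @seealso [countSpecies()], [overrideK()]
#' @export
setClass("SpeciesEstimate", representation(
  K = "integer",
  hits = "data.frame",
  method = "character"
))

setValidity("SpeciesEstimate", function(object) {
  if (length(object@K) != 1L || is.na(object@K) || object@K < 1L)
    return("K must be a positive integer")
  if (!object@method %in% c("reference_hits", "manual"))
    return("method must be 'reference_hits' or 'manual'")
  TRUE
})

#' Contig-to-cluster assignment
#'
#' The result of mixture-model binning: a hard assignment of every prepared
#' contig to one of K clusters plus the posterior responsibility matrix.
#'
#' @slot K integer number of clusters (cluster ids are 1..K; empty clusters
#'   are allowed).
#' @slot clusters named integer vector mapping contig id -> cluster id.
#' @slot responsibilities numeric matrix (contigs x K) of posterior weights.
#' @slot seed integer seed the model was fitted under.
#' @seealso [fitClusters()]
#' @export
setClass("ClusterAssignment", representation(
  K = "integer",
  clusters = "integer",
  responsibilities = "matrix",
  seed = "integer"
))

setValidity("ClusterAssignment", function(object) {
  if (object@K < 1L) return("K must be >= 1")
  if (is.null(names(object@clusters))) return("clusters must be named")
  if (any(object@clusters < 1L | object@clusters > object@K))
    return("cluster ids must lie in 1..K")
  if (nrow(object@responsibilities) != length(object@clusters))
    return("responsibility rows must match contig count")
  TRUE
})

#' Marker-identified target call
#'
#' Clusters flagged as the target species by marker-gene hits, the contigs
#' they contain, and the reads rescued by mapping onto those contigs.
#'
#' @slot targetClusters integer vector of target cluster ids (possibly
#'   several, empty when no target was found).
#' @slot targetContigs character vector: all contig ids of target clusters.
#' @slot rescuedReads character vector of read ids whose best alignment
#'   lands on a target contig.
#' @slot markerTally data.frame of distinct marker counts per cluster.
#' @slot noTarget logical: `TRUE` when no cluster passed the marker
#'   threshold (the pipeline halts cleanly on this, it is not an error).
#' @seealso [callTargetClusters()], [rescueReads()]
#' @export
setClass("TargetCall", representation(
  targetClusters = "integer",
  targetContigs = "character",
  rescuedReads = "character",
  markerTally = "data.frame",
  noTarget = "logical"
))

#' Full evaluation report
#'
#' All ground-truth evaluation quantities for one pipeline run: per-cluster
#' purity, target concentration across target clusters, read/contig
#' sensitivity and specificity, base- and gene-level coverage of the target
#' genome, and the per-stage data-loss ledger.
#'
#' @slot purity data.frame, one row per cluster.
#' @slot concentration data.frame, one row per (truth-defined) target
#'   cluster.
#' @slot dichotomy named numeric: sensitivity/specificity at contig and
#'   read level, in percent.
#' @slot coverage named numeric: mapped/total bases and genes plus the two
#'   coverage percentages.
#' @slot dataLoss data.frame of marginal and cumulative per-stage losses.
#' @slot ledger the raw stage ledger the losses were derived from.
#' @seealso [runPipeline()], [writeReportTables()]
#' @export
setClass("EvaluationReport", representation(
  purity = "data.frame",
  concentration = "data.frame",
  dichotomy = "numeric",
  coverage = "numeric",
  dataLoss = "data.frame",
  ledger = "data.frame"
))
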