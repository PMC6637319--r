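#' Align marker genes to contigs
#'
#' Built-in local aligner: exact 15-mer seeds shared between marker and
#' contig are extended ungapped in both directions (match +1, mismatch
#' -2, x-drop 20). Each hit's significance is an expectation value
#' computed with the standard Karlin-Altschul scaling
#' `E = K * m * n * exp(-lambda * S)`, where `S` is the raw score, `m`
#' the marker length, `n` the total contig bases, `lambda` the positive
#' root of `(1/4) exp(lambda) + (3/4) exp(-2 lambda) = 1` (about 1.33 for
#' +1/-2) and `K = 0.621`; hits with `E` above `evalue_cutoff` are
#' dropped. An external 12-column tabular hits file (query, subject,
#' percent identity, length, mismatches, gap opens, qstart, qend, sstart,
#' send, evalue, bitscore) can be supplied instead and is filtered at the
#' same cutoff.
#'
#' @param markers named [Biostrings::DNAStringSet] of marker genes
#'   (each >= 100 bp).
#' @param contigs a [ContigSet-class].
#' @param evalue_cutoff significance cutoff (default 1e-20).
#' @param seed_length exact seed length (default 15).
#' @param match,mismatch,xdrop extension scoring parameters.
#' @param hits_file optional external tabular hits file.
#' @param min_identity,min_length optional extra floors on hit identity
#'   and alignment length (defaults impose none).
#' @return data.frame of marker hits: `marker_id`, `contig_id`,
#'   `length`, `identity`, `score`, `bitscore`, `evalue`, `contig_start`,
#'   `contig_end`, `strand`.
#' @export
alignMarkers <- function(markers, contigs, evalue_cutoff = 1e-20,
                         seed_length = 15L, match = 1L, mismatch = 2L,
                         xdrop = 20L, hits_file = NULL,
                         min_identity = 0, min_length = 0L) {
  empty <- data.frame(marker_id = character(), contig_id = character(),
                      length = integer(), identity = numeric(),
                      score = integer(), bitscore = numeric(),
                      evalue = numeric(), contig_start = integer(),
                      contig_end = integer(), strand = character(),
                      stringsAsFactors = FALSE)
  if (!is.null(hits_file)) {
    tab <- utils::read.delim(hits_file, header = FALSE,
                             stringsAsFactors = FALSE, comment.char = "#")
    if (ncol(tab) < 12L)
      stop("external hits file must have 12 tabular columns", call. = FALSE)
    df <- data.frame(marker_id = as.character(tab[[1L]]),
                     contig_id = as.character(tab[[2L]]),
                     length = as.integer(tab[[4L]]),
                     identity = as.numeric(tab[[3L]]) / 100,
                     score = NA_integer_,
                     bitscore = as.numeric(tab[[12L]]),
                     evalue = as.numeric(tab[[11L]]),
                     contig_start = pmin(as.integer(tab[[9L]]), as.integer(tab[[10L]])),
                     contig_end = pmax(as.integer(tab[[9L]]), as.integer(tab[[10L]])),
                     strand = ifelse(tab[[10L]] >= tab[[9L]], "+", "-"),
                     stringsAsFactors = FALSE)
    df <- df[df$evalue <= evalue_cutoff &
             df$identity >= min_identity & df$length >= min_length, ,
             drop = FALSE]
    return(df[order(df$marker_id, df$contig_id, df$evalue), ])
  }
  if (length(markers) == 0L) stop("no marker genes supplied", call. = FALSE)
  if (is.null(names(markers)) || anyDuplicated(names(markers)))
    stop("markers must carry unique ids", call. = FALSE)
  if (any(Biostrings::width(markers) < 100L))
    stop("marker genes must be >= 100 bp", call. = FALSE)
  if (length(contigs) == 0L) {
    warning("empty contig set: no marker hits")
    return(empty)
  }
  hits <- .cpp_align_local(as.character(markers),
                           as.character(contigs@sequences),
                           seed_length, match, mismatch, xdrop)
  if (nrow(hits) == 0L) return(empty)
  lambda <- .karlin_lambda(match, mismatch)
  m_len <- Biostrings::width(markers)[hits$query]
  n_total <- sum(as.numeric(Biostrings::width(contigs@sequences)))
  evalue <- .KARLIN_K * m_len * n_total * exp(-lambda * hits$score)
  df <- data.frame(marker_id = names(markers)[hits$query],
                   contig_id = names(contigs@sequences)[hits$ref],
                   length = hits$length,
                   identity = hits$matches / hits$length,
                   score = hits$score,
                   bitscore = (lambda * hits$score - log(.KARLIN_K)) / log(2),
                   evalue = evalue,
                   contig_start = hits$ref_start,
                   contig_end = hits$ref_end,
                   strand = ifelse(hits$strand > 0L, "+", "-"),
                   stringsAsFactors = FALSE)
  df <- df[df$evalue <= evalue_cutoff &
           df$identity >= min_identity & df$length >= min_length, ,
           drop = FALSE]
  df[order(df$marker_id, df$contig_id, df$evalue), ]
}

#' Call target clusters from marker hits
#'
#' A cluster is called target when contigs assigned to it are hit by at
#' least `min_markers` distinct marker genes; all member contigs of the
#' called clusters become target contigs. Raising `min_markers` can only
#' shrink the called set. When no cluster qualifies, a `NO_TARGET` call is
#' returned (see [isNoTarget()]) rather than an error, so pipelines can
#' halt cleanly.
#'
#' @param hits marker hit table from [alignMarkers()].
#' @param assignment a [ClusterAssignment-class] over the same contigs.
#' @param min_markers minimum distinct markers per cluster (default 1).
#' @return a [TargetCall-class] (rescued reads not yet filled in).
#' @export
callTargetClusters <- function(hits, assignment, min_markers = 1L) {
  stopifnot(is(assignment, "ClusterAssignment"))
  min_markers <- .assert_scalar_int(min_markers, "min_markers", 1L)
  cl <- assignment@clusters
  if (nrow(hits) > 0L && !all(hits$contig_id %in% names(cl)))
    stop("marker hits refer to contigs absent from the assignment",
         call. = FALSE)
  tally <- data.frame(cluster = integer(), n_markers = integer())
  targets <- integer(0)
  if (nrow(hits) > 0L) {
    hit_cl <- cl[hits$contig_id]
    per <- tapply(hits$marker_id, hit_cl, function(m) length(unique(m)))
    tally <- data.frame(cluster = as.integer(names(per)),
                        n_markers = as.integer(per))
    tally <- tally[order(tally$cluster), , drop = FALSE]
    targets <- tally$cluster[tally$n_markers >= min_markers]
  }
  if (length(targets) == 0L) {
    message("NO_TARGET: no cluster reached ", min_markers,
            " distinct marker gene(s)")
    return(new("TargetCall", targetClusters = integer(0),
               targetContigs = character(0), rescuedReads = character(0),
               markerTally = tally, noTarget = TRUE))
  }
  new("TargetCall",
      targetClusters = targets,
      targetContigs = names(cl)[cl %in% targets],
      rescuedReads = character(0),
      markerTally = tally, noTarget = FALSE)
}

#' Rescue target reads
#'
#' Completes a [TargetCall-class]: reads whose best alignment lands on a
#' target contig are the rescued reads. When writing FASTQ, a pair is kept
#' if either mate qualifies and both mates are emitted (mate rescue),
#' preserving as much of the target's genomic information as possible.
#'
#' @param alignments read-to-contig table from [mapReads()].
#' @param call a [TargetCall-class] from [callTargetClusters()].
#' @param reads the [ReadSet-class] the alignments were computed from;
#'   needed for mate rescue and FASTQ output.
#' @param fastq_path optional path: write the rescued reads (with their
#'   mates) as FASTQ.
#' @return the completed [TargetCall-class].
#' @export
rescueReads <- function(alignments, call, reads, fastq_path = NULL) {
  stopifnot(is(call, "TargetCall"), is(reads, "ReadSet"))
  if (call@noTarget) return(call)
  resc <- alignments$read_id[alignments$contig_id %in% call@targetContigs]
  call@rescuedReads <- sort(unique(resc))
  if (!is.null(fastq_path)) {
    ids <- names(reads@sequences)
    take_pairs <- unique(reads@pairId[ids %in% call@rescuedReads])
    keep <- ids %in% call@rescuedReads |
      (reads@mate != 0L & reads@pairId %in% take_pairs)
    writeFastq(reads[which(keep)], fastq_path)
  }
  call
}
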