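#' Count species-level groups from rRNA similarity hits
#'
#' Estimates the number of species K used to fix the binning cluster
#' count. Each read is assigned to the best-matching taxon of a
#' user-supplied small-subunit rRNA reference when its best local
#' alignment reaches `min_identity` over at least `min_read_fraction` of
#' the read; K is the number of taxa collecting at least `min_hits`
#' assigned reads. Reads tying between taxa are counted for every tied
#' taxon (which can only add taxa, never remove them).
#'
#' @param reads a [ReadSet-class].
#' @param rrnaRef named [Biostrings::DNAStringSet] of rRNA reference
#'   sequences (one per taxon, each >= 200 bp).
#' @param min_identity minimum alignment identity.
#' @param min_hits minimum assigned reads for a taxon to count toward K.
#' @param min_read_fraction minimum aligned fraction of the read.
#' @return a [SpeciesEstimate-class]. When no taxon passes `min_hits`,
#'   K = 1 is returned with a warning (degenerate but usable).
#' @export
countSpecies <- function(reads, rrnaRef, min_identity = 0.95,
                         min_hits = 5L, min_read_fraction = 0.9) {
  stopifnot(is(reads, "ReadSet"))
  if (length(rrnaRef) == 0L)
    stop("empty rRNA reference", call. = FALSE)
  if (is.null(names(rrnaRef)) || anyDuplicated(names(rrnaRef)))
    stop("rRNA reference sequences must carry unique taxon names", call. = FALSE)
  if (any(Biostrings::width(rrnaRef) < 200L))
    stop("rRNA reference sequences must be >= 200 bp", call. = FALSE)
  min_hits <- .assert_scalar_int(min_hits, "min_hits", 1L)

  taxa <- names(rrnaRef)
  hits <- .cpp_align_local(as.character(rrnaRef),
                           as.character(reads@sequences),
                           15L, 1L, 2L, 20L)
  est_zero <- function() {
    warning("no taxon passed min_hits; returning degenerate K = 1")
    new("SpeciesEstimate", K = 1L,
        hits = data.frame(taxon_id = character(), n_reads = integer()),
        method = "reference_hits")
  }
  if (nrow(hits) == 0L) return(est_zero())

  rw <- Biostrings::width(reads@sequences)[hits$ref]
  hits$identity <- hits$matches / hits$length
  ok <- hits$identity >= min_identity & hits$length >= min_read_fraction * rw
  hits <- hits[ok, , drop = FALSE]
  if (nrow(hits) == 0L) return(est_zero())

  # best identity per read; ties credited to every tied taxon
  best <- stats::aggregate(identity ~ ref, data = hits, FUN = max)
  hits <- merge(hits, best, by = "ref", suffixes = c("", "_best"))
  hits <- hits[hits$identity >= hits$identity_best - 1e-12, , drop = FALSE]
  hits <- unique(hits[, c("ref", "query")])
  tally <- table(factor(taxa[hits$query], levels = taxa))
  counts <- data.frame(taxon_id = taxa, n_reads = as.integer(tally),
                       stringsAsFactors = FALSE)
  K <- sum(counts$n_reads >= min_hits)
  if (K == 0L) {
    warning("no taxon passed min_hits; returning degenerate K = 1")
    K <- 1L
  }
  new("SpeciesEstimate", K = as.integer(K), hits = counts,
      method = "reference_hits")
}

#' Set the cluster number manually
#'
#' @param k cluster count (>= 1).
#' @return a [SpeciesEstimate-class] with method `"manual"`.
#' @export
overrideK <- function(k) {
  k <- .assert_scalar_int(k, "k", 1L)
  new("SpeciesEstimate", K = k,
      hits = data.frame(taxon_id = character(), n_reads = integer()),
      method = "manual")
}
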