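#' Assemble unitigs from low-error reads
#'
#' A minimal de Bruijn assembler: canonical k-mers (a k-mer and its
#' reverse complement are identified) are counted over all reads, k-mers
#' seen fewer than `min_count` times are dropped as likely errors, and
#' maximal non-branching paths of the remaining graph are emitted as
#' unitigs in canonical orientation (the lexicographically smaller of the
#' two strands), longest first. K-mers containing N are skipped. The
#' assembler assumes low-error input; it performs no error correction
#' beyond the abundance filter.
#'
#' @param reads a [ReadSet-class].
#' @param k odd k-mer size, 1..31 (default 31).
#' @param min_count minimum k-mer multiplicity (default 2).
#' @return a [ContigSet-class] with ids `ctg00001`, ... in emission order;
#'   empty (with a warning) when no k-mer survives the filter.
#' @export
buildUnitigs <- function(reads, k = 31L, min_count = 2L) {
  stopifnot(is(reads, "ReadSet"))
  k <- .assert_scalar_int(k, "k", 1L)
  min_count <- .assert_scalar_int(min_count, "min_count", 1L)
  if (length(reads) > 0L && k >= min(Biostrings::width(reads@sequences)))
    stop("k must be smaller than the shortest read", call. = FALSE)
  seqs <- .cpp_build_unitigs(as.character(reads@sequences), k, min_count)
  seqs <- seqs[nchar(seqs) >= k]
  if (length(seqs) == 0L) {
    warning("no k-mer survived the abundance filter; empty assembly")
    return(.empty_contigs())
  }
  ids <- sprintf("ctg%05d", seq_along(seqs))
  new("ContigSet", sequences = .as_dss(seqs, ids),
      origin = rep("builtin", length(ids)),
      sourceContig = ids,
      coverage = matrix(numeric(0), nrow = 0L, ncol = 0L))
}

.empty_contigs <- function() {
  new("ContigSet", sequences = Biostrings::DNAStringSet(),
      origin = character(), sourceContig = character(),
      coverage = matrix(numeric(0), nrow = 0L, ncol = 0L))
}

#' Load externally assembled contigs
#'
#' Contigs from any assembler can replace [buildUnitigs()]; they still go
#' through [prepareContigs()] and [computeCoverage()] like built-in ones.
#'
#' @param x FASTA path or a named [Biostrings::DNAStringSet].
#' @return a [ContigSet-class] with origin `"external"`.
#' @export
externalContigs <- function(x) {
  seqs <- if (is(x, "DNAStringSet")) x else Biostrings::readDNAStringSet(x)
  if (is.null(names(seqs)))
    names(seqs) <- sprintf("ctg%05d", seq_along(seqs))
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  new("ContigSet", sequences = seqs,
      origin = rep("external", length(seqs)),
      sourceContig = names(seqs),
      coverage = matrix(numeric(0), nrow = 0L, ncol = 0L))
}

#' Length-window preparation of contigs for binning
#'
#' Contigs shorter than `min_len` are removed (low-quality assembly
#' products); contigs longer than `max_len` are split into consecutive
#' `max_len` pieces so that long contigs do not dominate the clustering.
#' When the final piece of a split would fall below `min_len` it is merged
#' into the previous piece (which may then exceed `max_len`); no base of a
#' surviving contig is ever discarded. The parent id is recorded in
#' `sourceContigs()`.
#'
#' @param contigs a [ContigSet-class].
#' @param min_len,max_len length window in bp (defaults 1000 and 10000).
#' @return a [ContigSet-class] of prepared pieces.
#' @export
prepareContigs <- function(contigs, min_len = 1000L, max_len = 10000L) {
  stopifnot(is(contigs, "ContigSet"))
  min_len <- .assert_scalar_int(min_len, "min_len", 1L)
  max_len <- .assert_scalar_int(max_len, "max_len", min_len)
  w <- Biostrings::width(contigs@sequences)
  keep <- which(w >= min_len)
  out_seq <- character(0)
  out_id <- character(0)
  out_src <- character(0)
  out_origin <- character(0)
  for (i in keep) {
    id <- names(contigs@sequences)[i]
    s <- as.character(contigs@sequences[[i]])
    len <- w[i]
    if (len <= max_len) {
      out_seq <- c(out_seq, s)
      out_id <- c(out_id, id)
      out_src <- c(out_src, id)
      out_origin <- c(out_origin, contigs@origin[i])
      next
    }
    n_piece <- len %/% max_len
    starts <- (seq_len(n_piece) - 1L) * max_len + 1L
    ends <- pmin(starts + max_len - 1L, len)
    tail_len <- len - ends[n_piece]
    if (tail_len >= min_len) {
      starts <- c(starts, ends[n_piece] + 1L)
      ends <- c(ends, len)
      n_piece <- n_piece + 1L
    } else if (tail_len > 0L) {
      ends[n_piece] <- len  # merge undersized tail into the last piece
    }
    out_seq <- c(out_seq, substring(s, starts, ends))
    out_id <- c(out_id, sprintf("%s.%d", id, seq_len(n_piece)))
    out_src <- c(out_src, rep(id, n_piece))
    out_origin <- c(out_origin, rep(contigs@origin[i], n_piece))
  }
  if (length(out_seq) == 0L) return(.empty_contigs())
  new("ContigSet", sequences = .as_dss(out_seq, out_id),
      origin = out_origin, sourceContig = out_src,
      coverage = matrix(numeric(0), nrow = 0L, ncol = 0L))
}

#' Map reads end-to-end onto contigs
#'
#' The built-in read mapper: an exact-seed table over the contigs (seed
#' length 21) proposes candidate placements, each candidate is verified
#' over the full read length, and the read is assigned to the placement
#' with the fewest mismatches subject to identity >= `min_identity`
#' (identity = 1 - mismatches / read length). Ties are broken by
#' lexicographically smallest contig id, then smallest position, then
#' forward strand. Unaligned reads are simply absent from the table.
#'
#' @param reads a [ReadSet-class].
#' @param contigs a [ContigSet-class] (or any named `DNAStringSet`-bearing
#'   reference, e.g. a genome, wrapped in a ContigSet).
#' @param min_identity minimum end-to-end identity (default 0.95).
#' @param seed_length exact seed length (default 21).
#' @return data.frame with columns `read_id`, `contig_id`, `start`, `end`
#'   (1-based closed, on the contig), `strand`, `mismatches`, `identity`.
#' @export
mapReads <- function(reads, contigs, min_identity = 0.95, seed_length = 21L) {
  stopifnot(is(reads, "ReadSet"), is(contigs, "ContigSet"))
  if (length(contigs) == 0L || length(reads) == 0L)
    return(data.frame(read_id = character(), contig_id = character(),
                      start = integer(), end = integer(),
                      strand = character(), mismatches = integer(),
                      identity = numeric(), stringsAsFactors = FALSE))
  # pass contigs in id order so the C++ lowest-index tie-break realises the
  # lowest-contig-id rule
  ord <- order(names(contigs@sequences), method = "radix")
  refs <- contigs@sequences[ord]
  hits <- .cpp_map_reads(as.character(reads@sequences),
                         as.character(refs), seed_length, min_identity)
  rl <- Biostrings::width(reads@sequences)[hits$read]
  data.frame(read_id = names(reads@sequences)[hits$read],
             contig_id = names(refs)[hits$ref],
             start = hits$start,
             end = hits$start + rl - 1L,
             strand = ifelse(hits$strand > 0L, "+", "-"),
             mismatches = hits$mismatches,
             identity = 1 - hits$mismatches / rl,
             stringsAsFactors = FALSE)
}

#' Per-contig mean read depth
#'
#' Mean per-base depth of each contig from a read-to-contig alignment
#' table, recorded as one coverage column (sample) on the contig set.
#' Depth is total aligned bases divided by contig length; doubling the
#' read set doubles it.
#'
#' @param contigs a [ContigSet-class].
#' @param alignments alignment table from [mapReads()].
#' @param sample_name coverage column name.
#' @return the [ContigSet-class] with the coverage column appended.
#' @export
computeCoverage <- function(contigs, alignments, sample_name = "sample1") {
  stopifnot(is(contigs, "ContigSet"))
  depth <- setNames(numeric(length(contigs)), names(contigs@sequences))
  if (nrow(alignments) > 0L) {
    bases <- rowsum(as.numeric(alignments$end - alignments$start + 1L),
                    alignments$contig_id)
    depth[rownames(bases)] <- bases[, 1L] /
      Biostrings::width(contigs@sequences)[match(rownames(bases),
                                                 names(contigs@sequences))]
  }
  cov <- contigs@coverage
  if (nrow(cov) == 0L) cov <- matrix(numeric(0), nrow = length(contigs), ncol = 0L)
  cov <- cbind(cov, matrix(depth, ncol = 1L,
                           dimnames = list(NULL, sample_name)))
  contigs@coverage <- cov
  contigs
}

#' Assembly summary statistics
#'
#' Contig count, N50 (the length at which cumulative length in descending
#' order first reaches half the total), mean length and total bases.
#'
#' @param contigs a non-empty [ContigSet-class].
#' @return named list with `n_contigs`, `n50`, `mean_length`,
#'   `total_bases`.
#' @export
assemblyStats <- function(contigs) {
  stopifnot(is(contigs, "ContigSet"))
  if (length(contigs) == 0L)
    stop("assembly statistics are undefined for an empty contig set",
         call. = FALSE)
  w <- sort(Biostrings::width(contigs@sequences), decreasing = TRUE)
  total <- sum(as.numeric(w))
  n50 <- w[which(cumsum(as.numeric(w)) >= total / 2)[1L]]
  list(n_contigs = length(w), n50 = as.integer(n50),
       mean_length = total / length(w), total_bases = total)
}
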