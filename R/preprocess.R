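#' Trimming parameters
#'
#' Leading/trailing quality trimming in the style of Trimmomatic's
#' LEADING/TRAILING steps: terminal bases are removed one by one while
#' their quality is below the threshold, and reads shorter than
#' `min_length` after trimming are discarded. An optional fixed-cut mode
#' unconditionally removes a set number of bases from each end instead.
#'
#' @param quality_threshold phred threshold (default 3).
#' @param min_length minimum surviving read length in bp (default 50).
#' @param fixed_cut if non-`NULL`, cut exactly this many bases from each
#'   end instead of quality-driven trimming.
#' @return a validated list of class `TrimParams`.
#' @export
trimParams <- function(quality_threshold = 3L, min_length = 50L,
                       fixed_cut = NULL) {
  quality_threshold <- .assert_scalar_int(quality_threshold, "quality_threshold", 0L)
  min_length <- .assert_scalar_int(min_length, "min_length", 1L)
  if (!is.null(fixed_cut))
    fixed_cut <- .assert_scalar_int(fixed_cut, "fixed_cut", 0L)
  structure(list(quality_threshold = quality_threshold,
                 min_length = min_length, fixed_cut = fixed_cut),
            class = "TrimParams")
}

#' Quality-trim a read set
#'
#' Applies [trimParams()] trimming to every read. Pairs where either mate
#' is discarded are dropped entirely (both mates), keeping downstream
#' pair-aware stages simple; single reads are discarded individually.
#' Trimming is idempotent and raising the threshold never increases the
#' survivor count.
#'
#' @param reads a [ReadSet-class].
#' @param params a [trimParams()].
#' @param truth optional truth table; when given, target-read counts are
#'   recorded in the ledger entry.
#' @return `list(reads = ReadSet, ledger = data.frame)` where the ledger
#'   row counts reads entering and surviving the stage.
#' @export
trimReads <- function(reads, params = trimParams(), truth = NULL) {
  stopifnot(is(reads, "ReadSet"))
  n <- length(reads)
  if (n == 0L) {
    led <- .ledger_row("trim", 0L, 0L, if (!is.null(truth)) 0L, if (!is.null(truth)) 0L)
    return(list(reads = reads, ledger = led))
  }
  widths <- Biostrings::width(reads@sequences)
  quals <- as.character(reads@quality)

  if (!is.null(params$fixed_cut)) {
    starts <- rep(params$fixed_cut + 1L, n)
    ends <- widths - params$fixed_cut
  } else {
    th <- params$quality_threshold
    starts <- rep(1L, n)
    ends <- widths
    if (th > 0L) {
      # fast path: reads whose minimum quality already meets the threshold
      # are untouched; only flagged reads are scanned base by base
      low_class <- sprintf("[\\x21-\\x%02X]", .PHRED_MIN_CHAR + th - 1L)
      flagged <- which(grepl(low_class, quals, perl = TRUE, useBytes = TRUE))
      for (i in flagged) {
        q <- .phred_to_int(quals[i])
        keep <- which(q >= th)
        if (length(keep) == 0L) { starts[i] <- 1L; ends[i] <- 0L; next }
        starts[i] <- keep[1L]
        ends[i] <- keep[length(keep)]
      }
    }
  }
  new_w <- pmax(ends - starts + 1L, 0L)
  ok <- new_w >= params$min_length
  # orphan policy: drop both mates when one fails
  paired <- reads@mate != 0L
  bad_pairs <- unique(reads@pairId[paired & !ok])
  keep <- ok & !(paired & reads@pairId %in% bad_pairs)

  idx <- which(keep)
  seqs <- Biostrings::subseq(reads@sequences[idx], start = starts[idx],
                             end = ends[idx])
  qual <- Biostrings::PhredQuality(substring(quals[idx], starts[idx], ends[idx]))
  out <- new("ReadSet", sequences = seqs, quality = qual,
             mate = reads@mate[idx], pairId = reads@pairId[idx])
  led <- if (is.null(truth)) {
    .ledger_row("trim", n, length(idx))
  } else {
    tgt <- truth$read_id[truth$role == "target"]
    .ledger_row("trim", n, length(idx),
                sum(names(reads@sequences) %in% tgt),
                sum(names(out@sequences) %in% tgt))
  }
  list(reads = out, ledger = led)
}

.ledger_row <- function(stage, reads_in, reads_out,
                        target_in = NULL, target_out = NULL) {
  df <- data.frame(stage = stage, reads_in = reads_in, reads_out = reads_out,
                   stringsAsFactors = FALSE)
  if (!is.null(target_in)) {
    df$target_in <- target_in
    df$target_out <- target_out
  }
  df
}
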