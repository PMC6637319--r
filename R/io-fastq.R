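#' Read FASTQ files into a ReadSet
#'
#' Parses 4-line FASTQ records with phred+33 qualities. When `paired_path`
#' is given, the two files are read as mate 1 and mate 2 and the result is
#' interleaved by pair. Gzip-compressed files are handled transparently.
#' Quality characters above `'K'` (phred 42) are rejected as likely
#' phred+64 input; phred encodings are never auto-detected.
#'
#' @param path FASTQ file (mate 1 when paired).
#' @param paired_path optional mate-2 FASTQ file.
#' @return a [ReadSet-class].
#' @examples
#' fq <- tempfile(fileext = ".fastq")
#' writeLines(c("@r1", "ACGT", "+", "IIII"), fq)
#' rs <- readFastq(fq)
#' as.integer(readQualities(rs)[[1]])  # 40 40 40 40
#' @export
readFastq <- function(path, paired_path = NULL) {
  r1 <- .parse_fastq(path)
  if (is.null(paired_path)) {
    return(new("ReadSet",
               sequences = .as_dss(r1$seq, r1$id),
               quality = Biostrings::PhredQuality(r1$qual),
               mate = rep(0L, length(r1$id)),
               pairId = r1$id))
  }
  r2 <- .parse_fastq(paired_path)
  if (length(r1$id) != length(r2$id))
    stop(sprintf("paired files differ in record count (%d vs %d)",
                 length(r1$id), length(r2$id)), call. = FALSE)
  p1 <- sub("/[12]$", "", r1$id)
  p2 <- sub("/[12]$", "", r2$id)
  if (!all(p1 == p2))
    stop("mate files are not in matching pair order", call. = FALSE)
  n <- length(p1)
  # interleave r1[i], r2[i]
  seqs <- character(2L * n)
  quals <- character(2L * n)
  ids <- character(2L * n)
  seqs[c(TRUE, FALSE)] <- r1$seq;  seqs[c(FALSE, TRUE)] <- r2$seq
  quals[c(TRUE, FALSE)] <- r1$qual; quals[c(FALSE, TRUE)] <- r2$qual
  ids[c(TRUE, FALSE)] <- r1$id;    ids[c(FALSE, TRUE)] <- r2$id
  if (anyDuplicated(ids)) {
    # mate files that reuse the bare fragment name get /1 /2 suffixes
    ids[c(TRUE, FALSE)] <- paste0(p1, "/1")
    ids[c(FALSE, TRUE)] <- paste0(p2, "/2")
  }
  new("ReadSet",
      sequences = .as_dss(seqs, ids),
      quality = Biostrings::PhredQuality(quals),
      mate = rep(1:2, n),
      pairId = rep(p1, each = 2L))
}

.as_dss <- function(seqs, ids) {
  x <- Biostrings::DNAStringSet(seqs)
  names(x) <- ids
  x
}

.parse_fastq <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  n <- length(lines)
  if (n == 0L)
    return(list(id = character(), seq = character(), qual = character()))
  if (n %% 4L != 0L)
    .stop_io(path, n, "truncated FASTQ: record count is not a multiple of 4")
  hdr <- lines[c(TRUE, FALSE, FALSE, FALSE)]
  seq <- lines[c(FALSE, TRUE, FALSE, FALSE)]
  sep <- lines[c(FALSE, FALSE, TRUE, FALSE)]
  qual <- lines[c(FALSE, FALSE, FALSE, TRUE)]
  bad <- which(substr(hdr, 1L, 1L) != "@")
  if (length(bad))
    .stop_io(path, (bad[1L] - 1L) * 4L + 1L, "expected '@' header line")
  bad <- which(substr(sep, 1L, 1L) != "+")
  if (length(bad))
    .stop_io(path, (bad[1L] - 1L) * 4L + 3L, "expected '+' separator line")
  bad <- which(nchar(seq) != nchar(qual))
  if (length(bad))
    .stop_io(path, (bad[1L] - 1L) * 4L + 4L,
             "quality length differs from sequence length")
  bad <- which(grepl("[^ACGTNacgtn]", seq))
  if (length(bad))
    .stop_io(path, (bad[1L] - 1L) * 4L + 2L, "non-ACGTN base in sequence")
  bad <- which(grepl(sprintf("[^\\x21-\\x%X]", .PHRED_MAX_CHAR), qual,
                     perl = TRUE, useBytes = TRUE))
  if (length(bad))
    .stop_io(path, (bad[1L] - 1L) * 4L + 4L,
             "quality character above phred+33 range (phred+64 input is rejected)")
  ids <- sub("\\s.*$", "", substring(hdr, 2L))
  list(id = ids, seq = toupper(seq), qual = qual)
}

#' Write a ReadSet to FASTQ
#'
#' Emits 4-line phred+33 records. With `paired_path`, mate-1 reads go to
#' `path` and mate-2 reads to `paired_path`; otherwise all reads are
#' written (interleaved, in set order) to `path`. `write(read(x))` is
#' byte-identical to `x` for well-formed input with bare read ids.
#'
#' @param reads a [ReadSet-class].
#' @param path output FASTQ (mate 1 when `paired_path` is given).
#' @param paired_path optional mate-2 output FASTQ.
#' @return invisibly, the path(s) written.
#' @export
writeFastq <- function(reads, path, paired_path = NULL) {
  stopifnot(is(reads, "ReadSet"))
  emit <- function(x, p) {
    ids <- names(x@sequences)
    rec <- character(4L * length(x))
    rec[c(TRUE, FALSE, FALSE, FALSE)] <- paste0("@", ids)
    rec[c(FALSE, TRUE, FALSE, FALSE)] <- as.character(x@sequences)
    rec[c(FALSE, FALSE, TRUE, FALSE)] <- "+"
    rec[c(FALSE, FALSE, FALSE, TRUE)] <- as.character(x@quality)
    writeLines(rec, p)
  }
  if (is.null(paired_path)) {
    emit(reads, path)
    return(invisible(path))
  }
  emit(reads[reads@mate == 1L], path)
  emit(reads[reads@mate == 2L], paired_path)
  invisible(c(path, paired_path))
}

#' Read a ground-truth table
#'
#' A truth table maps every simulated read to its source species and that
#' species' role. Stored as TSV with columns `read_id`, `species_id`,
#' `role` (role is `target` or `contaminant`).
#'
#' @param path TSV file.
#' @return data.frame with the three columns above.
#' @export
readTruth <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  .validate_truth(df)
}

#' @rdname readTruth
#' @param truth a truth data.frame.
#' @export
writeTruth <- function(truth, path) {
  truth <- .validate_truth(truth)
  utils::write.table(truth, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.validate_truth <- function(df) {
  need <- c("read_id", "species_id", "role")
  if (!all(need %in% names(df)))
    stop("truth table must have columns read_id, species_id, role", call. = FALSE)
  if (anyDuplicated(df$read_id))
    stop("truth table: duplicated read_id", call. = FALSE)
  if (!all(df$role %in% c("target", "contaminant")))
    stop("truth table: role must be 'target' or 'contaminant'", call. = FALSE)
  df[need]
}
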