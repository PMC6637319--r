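# Internal helpers shared across modules.

# phred+33 encoding bounds: '!' (Q0) .. 'K' (Q42). Anything above 'K' is
# taken as evidence of phred+64 input, which is rejected rather than
# auto-detected.
.PHRED_MIN_CHAR <- 33L
.PHRED_MAX_CHAR <- 75L

.phred_to_int <- function(qual_string) {
  utf8ToInt(qual_string) - .PHRED_MIN_CHAR
}

.int_to_phred <- function(scores) {
  intToUtf8(scores + .PHRED_MIN_CHAR)
}

.revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

.assert_scalar_int <- function(x, name, min = NULL) {
  if (length(x) != 1L || is.na(x) || x != as.integer(x))
    stop(sprintf("'%s' must be a single integer", name), call. = FALSE)
  if (!is.null(min) && x < min)
    stop(sprintf("'%s' must be >= %d", name, min), call. = FALSE)
  invisible(as.integer(x))
}

# Karlin-Altschul lambda for an ungapped match/mismatch scoring scheme under
# uniform base composition: the unique positive root of
#   sum_ij p_i p_j exp(lambda * s_ij) = 1
# which for match score +a, mismatch score -b and p = 1/4 reduces to
#   (1/4) exp(lambda a) + (3/4) exp(-lambda b) = 1.
.karlin_lambda <- function(match, mismatch) {
  f <- function(l) 0.25 * exp(l * match) + 0.75 * exp(-l * mismatch) - 1
  stats::uniroot(f, c(1e-6, 10), tol = 1e-12)$root
}

# Karlin-Altschul K for ungapped DNA alignments; the BLASTN value for the
# +1/-2 scheme is used as a fixed constant (the e-value filter is a hard
# cutoff many orders of magnitude away from borderline hits, so the exact K
# matters little).
.KARLIN_K <- 0.621

.stop_io <- function(path, line, msg) {
  stop(sprintf("%s:%d: %s", path, line, msg), call. = FALSE)
}
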