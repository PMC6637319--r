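# Fixture builders shared across the suite. Everything is generated in
# code; no data files.

# a ReadSet from bare character vectors (constant Q40 unless given)
make_reads <- function(seqs, ids = sprintf("r%03d", seq_along(seqs)),
                       quals = NULL, mate = NULL, pair_id = NULL) {
  if (is.null(quals)) quals <- strrep("I", nchar(seqs))
  if (is.null(mate)) mate <- rep(0L, length(seqs))
  if (is.null(pair_id)) pair_id <- ids
  dss <- Biostrings::DNAStringSet(seqs)
  names(dss) <- ids
  new("ReadSet", sequences = dss,
      quality = Biostrings::PhredQuality(quals),
      mate = as.integer(mate), pairId = pair_id)
}

make_contigs <- function(seqs, ids = sprintf("ctg%05d", seq_along(seqs)),
                         origin = "builtin") {
  dss <- Biostrings::DNAStringSet(seqs)
  names(dss) <- ids
  new("ContigSet", sequences = dss,
      origin = rep(origin, length(seqs)), sourceContig = ids,
      coverage = matrix(numeric(0), 0L, 0L))
}

random_seq <- function(n, seed, gc = 0.5) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

revcomp <- function(x)
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))

# error-free reads tiling a sequence at the given stride, both strands
# covered implicitly by the assembler's canonicalisation
tile_reads <- function(seq, read_len = 60L, stride = 2L) {
  starts <- seq.int(1L, nchar(seq) - read_len + 1L, by = stride)
  make_reads(substring(seq, starts, starts + read_len - 1L),
             ids = sprintf("t%05d", seq_along(starts)))
}

# Independent oracle: brute-force unitig enumeration on the canonical
# de Bruijn graph, in plain R. Mirrors the definition (maximal
# non-branching paths), not the implementation.
oracle_unitigs <- function(reads, k, min_count = 1L) {
  canon <- function(s) {
    r <- revcomp(s)
    ifelse(s <= r, s, r)
  }
  kmers_of <- function(s) {
    if (nchar(s) < k) return(character(0))
    substring(s, seq_len(nchar(s) - k + 1L), seq_len(nchar(s) - k + 1L) + k - 1L)
  }
  all_k <- unlist(lapply(reads, kmers_of))
  all_k <- all_k[!grepl("N", all_k)]
  tab <- table(canon(all_k))
  nodes <- sort(names(tab)[tab >= min_count])
  if (length(nodes) == 0L) return(character(0))
  in_graph <- function(s) canon(s) %in% nodes
  succs <- function(s) {
    cand <- paste0(substring(s, 2L), c("A", "C", "G", "T"))
    cand[in_graph(cand)]
  }
  preds <- function(s) {
    cand <- paste0(c("A", "C", "G", "T"), substring(s, 1L, k - 1L))
    cand[in_graph(cand)]
  }
  used <- new.env()
  out <- character(0)
  for (start in nodes) {
    if (!is.null(used[[start]])) next
    used[[start]] <- TRUE
    walk <- function(s0) {
      path <- character(0)
      cur <- s0
      repeat {
        nx <- succs(cur)
        if (length(nx) != 1L) break
        if (length(preds(nx)) != 1L) break
        if (!is.null(used[[canon(nx)]])) break
        used[[canon(nx)]] <- TRUE
        path <- c(path, substring(nx, k, k))
        cur <- nx
      }
      path
    }
    right <- walk(start)
    left <- walk(revcomp(start))
    seq <- paste0(revcomp(paste(left, collapse = "")), start,
                  paste(right, collapse = ""))
    rc <- revcomp(seq)
    out <- c(out, if (seq <= rc) seq else rc)
  }
  sort(out)
}
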