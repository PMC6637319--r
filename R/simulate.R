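#' Simulation configuration
#'
#' Parameters of the paired-read community simulator. Defaults follow the
#' simulated study design this package emulates: 120 bp paired reads on
#' 200 bp fragments at 100-fold coverage of the genome pool, error-free.
#'
#' @param read_length read length in bp.
#' @param fragment_length fragment (insert) length in bp; constant, with
#'   fragment starts drawn uniformly along the genome. Must be >=
#'   `read_length`.
#' @param coverage fold coverage of the total genome pool (sum of all
#'   genome lengths); determines the pair count
#'   `N = coverage * sum(lengths) / (2 * read_length)`.
#' @param error_rate per-base substitution probability (no indels).
#' @param seed integer RNG seed.
#' @param tiled if `TRUE`, fragments tile each genome deterministically
#'   every `fragment_length` bp instead of being drawn uniformly (coverage
#'   is then ignored).
#' @return a validated list of class `SimConfig`.
#' @export
simConfig <- function(read_length = 120L, fragment_length = 200L,
                      coverage = 100, error_rate = 0, seed = 1L,
                      tiled = FALSE) {
  read_length <- .assert_scalar_int(read_length, "read_length", 1L)
  fragment_length <- .assert_scalar_int(fragment_length, "fragment_length", 1L)
  if (read_length > fragment_length)
    stop("read_length must be <= fragment_length", call. = FALSE)
  if (coverage <= 0) stop("coverage must be > 0", call. = FALSE)
  if (error_rate < 0 || error_rate >= 1)
    stop("error_rate must be in [0, 1)", call. = FALSE)
  structure(list(read_length = read_length,
                 fragment_length = fragment_length,
                 coverage = coverage, error_rate = error_rate,
                 seed = .assert_scalar_int(seed, "seed"), tiled = tiled),
            class = "SimConfig")
}

#' Generate a random genome
#'
#' I.i.d. bases with the requested GC content; a stand-in for a real
#' bacterial genome in simulations.
#'
#' @param length genome length in bp (>= 1000; anything shorter cannot be
#'   fragmented and binned meaningfully).
#' @param gc GC fraction, strictly between 0 and 1.
#' @param seed integer RNG seed; the same seed gives the same genome.
#' @param species_id,role,read_proportion fields of the resulting
#'   [GenomeSpec-class].
#' @return a [GenomeSpec-class].
#' @export
makeRandomGenome <- function(length, gc, seed, species_id = "genome1",
                             role = c("contaminant", "target"),
                             read_proportion = 1) {
  role <- match.arg(role)
  length <- .assert_scalar_int(length, "length", 1000L)
  if (!is.numeric(gc) || length(gc) != 1L || gc <= 0 || gc >= 1)
    stop("gc must lie strictly between 0 and 1", call. = FALSE)
  set.seed(.assert_scalar_int(seed, "seed"))
  bases <- sample(c("A", "C", "G", "T"), length, replace = TRUE,
                  prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
  new("GenomeSpec", speciesId = species_id,
      sequence = Biostrings::DNAString(paste(bases, collapse = "")),
      role = role, readProportion = read_proportion,
      planted = GenomicRanges::GRanges(), genes = GenomicRanges::GRanges())
}

#' Plant sequences (marker genes, rRNA) into a genome
#'
#' Each sequence is inserted verbatim at a random position; insertions are
#' non-overlapping and their final coordinates are recorded in the
#' `planted` slot, so every planted feature is recoverable by exact
#' substring search. The genome grows by the total planted length.
#'
#' @param genome a [GenomeSpec-class].
#' @param features named [Biostrings::DNAStringSet] to insert.
#' @param seed integer RNG seed.
#' @return the genome with the features inserted and recorded.
#' @export
plantMarkerGenes <- function(genome, features, seed) {
  stopifnot(is(genome, "GenomeSpec"))
  if (length(features) == 0L) return(genome)
  if (is.null(names(features)) || anyDuplicated(names(features)))
    stop("features must carry unique names", call. = FALSE)
  glen <- length(genome@sequence)
  if (glen < sum(Biostrings::width(features)))
    stop("insufficient room: genome shorter than total planted length",
         call. = FALSE)
  set.seed(.assert_scalar_int(seed, "seed"))
  n <- length(features)
  # insertion points in original coordinates, distinct and sorted
  pts <- sort(sample.int(glen - 1L, n))
  seqs <- as.character(features)
  widths <- Biostrings::width(features)
  gseq <- as.character(genome@sequence)
  pieces <- character(2L * n + 1L)
  prev <- 0L
  starts <- integer(n)
  offset <- 0L
  for (i in seq_len(n)) {
    pieces[2L * i - 1L] <- substring(gseq, prev + 1L, pts[i])
    pieces[2L * i] <- seqs[i]
    starts[i] <- pts[i] + offset + 1L
    offset <- offset + widths[i]
    prev <- pts[i]
  }
  pieces[2L * n + 1L] <- substring(gseq, prev + 1L, glen)
  planted <- GenomicRanges::GRanges(
    genome@speciesId,
    IRanges::IRanges(start = starts, width = widths))
  S4Vectors::mcols(planted)$feature_id <- names(features)
  genome@sequence <- Biostrings::DNAString(paste(pieces, collapse = ""))
  # earlier planted/gene coordinates would be invalidated by the insertions;
  # plant features before annotating genes
  if (length(genome@planted) || length(genome@genes))
    stop("plant features before annotating genes or further features",
         call. = FALSE)
  genome@planted <- planted
  genome
}

#' Annotate random non-overlapping gene intervals
#'
#' Marks `n` disjoint intervals of the existing genome sequence as genes
#' (no sequence is inserted), providing the annotation used by gene-level
#' coverage evaluation.
#'
#' @param genome a [GenomeSpec-class].
#' @param n number of genes.
#' @param gene_length gene length in bp.
#' @param seed integer RNG seed.
#' @return the genome with the `genes` slot filled.
#' @export
plantGenes <- function(genome, n, gene_length, seed) {
  stopifnot(is(genome, "GenomeSpec"))
  n <- .assert_scalar_int(n, "n", 0L)
  if (n == 0L) return(genome)
  gene_length <- .assert_scalar_int(gene_length, "gene_length", 1L)
  glen <- length(genome@sequence)
  if (n * gene_length > glen)
    stop("insufficient room for the requested genes", call. = FALSE)
  set.seed(.assert_scalar_int(seed, "seed"))
  # draw disjoint intervals: place n blocks into the free space
  free <- glen - n * gene_length
  gaps <- sort(sample.int(free + 1L, n, replace = TRUE)) - 1L
  starts <- gaps + (seq_len(n) - 1L) * gene_length + 1L
  genes <- GenomicRanges::GRanges(
    genome@speciesId, IRanges::IRanges(start = starts, width = gene_length))
  S4Vectors::mcols(genes)$gene_id <- sprintf("gene%03d", seq_len(n))
  genome@genes <- genes
  genome
}

#' Simulate a contaminated paired-read community
#'
#' Draws `N = coverage * sum(genome lengths) / (2 * read_length)` read
#' pairs; each pair's genome is chosen with probability equal to its
#' `readProportion`, the fragment start is uniform, mate 1 is the leading
#' `read_length` bases of the fragment and mate 2 the reverse complement
#' of its trailing `read_length` bases. All qualities are phred 40.
#' Exactly one genome must have role `target` and proportions must sum
#' to 1.
#'
#' @param genomes list of [GenomeSpec-class] objects.
#' @param config a [simConfig()].
#' @return `list(reads = ReadSet, truth = data.frame)`; the truth table has
#'   one row per read (2N rows).
#' @export
simulateReads <- function(genomes, config = simConfig()) {
  stopifnot(all(vapply(genomes, is, TRUE, "GenomeSpec")))
  props <- vapply(genomes, function(g) g@readProportion, 0)
  roles <- vapply(genomes, function(g) g@role, "")
  if (abs(sum(props) - 1) > 1e-9)
    stop("read proportions must sum to 1", call. = FALSE)
  if (sum(roles == "target") != 1L)
    stop("exactly one genome must have role 'target'", call. = FALSE)
  glens <- vapply(genomes, function(g) length(g@sequence), 0L)
  frag <- config$fragment_length
  rl <- config$read_length
  if (any(glens < frag))
    stop("fragment length exceeds a genome length", call. = FALSE)

  set.seed(config$seed)
  if (config$tiled) {
    counts <- vapply(glens, function(L) length(seq.int(1L, L - frag + 1L, by = frag)), 0L)
    n_pairs <- sum(counts)
  } else {
    n_pairs <- as.integer(round(config$coverage * sum(glens) / (2 * rl)))
    counts <- as.integer(stats::rmultinom(1L, n_pairs, props))
  }

  ids <- vector("list", length(genomes))
  m1 <- vector("list", length(genomes))
  m2 <- vector("list", length(genomes))
  sp <- character(0)
  done <- 0L
  for (gi in seq_along(genomes)) {
    cnt <- counts[gi]
    if (cnt == 0L) { ids[[gi]] <- character(0); m1[[gi]] <- m2[[gi]] <- character(0); next }
    L <- glens[gi]
    starts <- if (config$tiled) seq.int(1L, L - frag + 1L, by = frag)
              else sample.int(L - frag + 1L, cnt, replace = TRUE)
    gseq <- as.character(genomes[[gi]]@sequence)
    a <- substring(gseq, starts, starts + rl - 1L)
    b <- .revcomp_chr(substring(gseq, starts + frag - rl, starts + frag - 1L))
    if (config$error_rate > 0) {
      a <- .mutate_reads(a, config$error_rate)
      b <- .mutate_reads(b, config$error_rate)
    }
    ids[[gi]] <- sprintf("p%07d", done + seq_len(cnt))
    m1[[gi]] <- a
    m2[[gi]] <- b
    done <- done + cnt
  }
  pair_ids <- unlist(ids, use.names = FALSE)
  species <- rep(vapply(genomes, function(g) g@speciesId, ""), counts)
  n <- length(pair_ids)
  seqs <- character(2L * n)
  seqs[c(TRUE, FALSE)] <- unlist(m1, use.names = FALSE)
  seqs[c(FALSE, TRUE)] <- unlist(m2, use.names = FALSE)
  read_ids <- character(2L * n)
  read_ids[c(TRUE, FALSE)] <- paste0(pair_ids, "/1")
  read_ids[c(FALSE, TRUE)] <- paste0(pair_ids, "/2")
  qual <- strrep(intToUtf8(40L + 33L), rl)
  reads <- new("ReadSet",
               sequences = .as_dss(seqs, read_ids),
               quality = Biostrings::PhredQuality(rep(qual, 2L * n)),
               mate = rep(1:2, n),
               pairId = rep(pair_ids, each = 2L))
  truth <- data.frame(read_id = read_ids,
                      species_id = rep(species, each = 2L),
                      role = rep(rep(roles, counts), each = 2L),
                      stringsAsFactors = FALSE)
  list(reads = reads, truth = truth)
}

.mutate_reads <- function(seqs, rate) {
  n_mut <- stats::rbinom(length(seqs), nchar(seqs), rate)
  hit <- which(n_mut > 0L)
  for (i in hit) {
    pos <- sample.int(nchar(seqs[i]), n_mut[i])
    chars <- strsplit(seqs[i], NULL)[[1L]]
    for (p in pos)
      chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1L)
    seqs[i] <- paste(chars, collapse = "")
  }
  seqs
}

#' Build the standard synthetic community
#'
#' Constructs the study community the package's evaluations run on: one
#' target genome (default 200 kb, GC 0.50) carrying planted marker genes
#' and gene annotations, plus GC-separated contaminant genomes (default
#' ten of 100 kb at GC 0.25..0.75 in steps of 0.05, skipping the target's
#' 0.50). Marker sequences are rejection-sampled so that no marker shares
#' a 15-mer with any contaminant genome (in either orientation), which
#' makes marker-based target calling specific by construction. Optionally
#' a distinct rRNA-like sequence is inserted into every genome and
#' returned as the reference for species counting.
#'
#' @param seed integer RNG seed.
#' @param n_contaminants number of contaminant genomes.
#' @param target_length,contaminant_length genome lengths in bp.
#' @param n_markers,marker_length planted marker genes in the target.
#' @param n_genes,gene_length annotated gene intervals in the target.
#' @param with_rrna also plant per-species rRNA-like sequences and return
#'   their reference set.
#' @param rrna_length rRNA sequence length in bp.
#' @return list with elements `genomes` (list of [GenomeSpec-class], the
#'   target first, proportions unset), `markers` ([Biostrings::DNAStringSet]),
#'   `annotation` (`GRanges` of target genes) and `rrnaRef` (DNAStringSet or
#'   `NULL`).
#' @export
communityPreset <- function(seed, n_contaminants = 10L,
                            target_length = 200000L,
                            contaminant_length = 100000L,
                            n_markers = 5L, marker_length = 600L,
                            n_genes = 50L, gene_length = 900L,
                            with_rrna = FALSE, rrna_length = 1500L) {
  seed <- .assert_scalar_int(seed, "seed")
  gc_grid <- setdiff(seq(0.25, 0.75, by = 0.05), 0.50)
  if (n_contaminants > length(gc_grid))
    stop(sprintf("at most %d contaminants supported by the GC grid",
                 length(gc_grid)), call. = FALSE)
  gcs <- gc_grid[seq_len(n_contaminants)]

  contams <- vector("list", n_contaminants)
  for (i in seq_len(n_contaminants))
    contams[[i]] <- makeRandomGenome(contaminant_length, gcs[i],
                                     seed = seed + i,
                                     species_id = sprintf("contam%02d", i),
                                     role = "contaminant")
  target <- makeRandomGenome(target_length, 0.50, seed = seed + 1000L,
                             species_id = "target", role = "target")

  # markers: random sequences sharing no 15-mer with any contaminant
  contam_seqs <- Biostrings::DNAStringSet(
    vapply(contams, function(g) as.character(g@sequence), ""))
  markers <- .draw_clean_markers(n_markers, marker_length, contam_seqs,
                                 seed + 2000L)
  rrna <- NULL
  feats <- markers
  if (with_rrna) {
    set.seed(seed + 3000L)
    rrna_ids <- c("target", vapply(contams, function(g) g@speciesId, ""))
    rrna <- Biostrings::DNAStringSet(vapply(rrna_ids, function(id)
      paste(sample(c("A", "C", "G", "T"), rrna_length, replace = TRUE),
            collapse = ""), ""))
    names(rrna) <- rrna_ids
    feats <- c(markers, rrna["target"])
    names(feats) <- c(names(markers), "rrna_target")
    for (i in seq_len(n_contaminants)) {
      f <- rrna[rrna_ids[i + 1L]]
      names(f) <- paste0("rrna_", rrna_ids[i + 1L])
      contams[[i]] <- plantMarkerGenes(contams[[i]], f, seed + 4000L + i)
    }
  }
  target <- plantMarkerGenes(target, feats, seed + 5000L)
  target <- plantGenes(target, n_genes, gene_length, seed + 6000L)

  list(genomes = c(list(target), contams), markers = markers,
       annotation = target@genes, rrnaRef = rrna)
}

# rejection-sample marker sequences until none shares a 15-mer (either
# strand) with any contaminant genome
.draw_clean_markers <- function(n, len, contam_seqs, seed) {
  set.seed(seed)
  out <- character(n)
  for (i in seq_len(n)) {
    repeat {
      cand <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
                    collapse = "")
      wins <- substring(cand, seq_len(len - 14L), seq_len(len - 14L) + 14L)
      pd <- Biostrings::DNAStringSet(unique(c(wins, .revcomp_chr(wins))))
      hits <- Biostrings::vcountPDict(Biostrings::PDict(pd), contam_seqs)
      if (sum(hits) == 0L) break
    }
    out[i] <- cand
  }
  ms <- Biostrings::DNAStringSet(out)
  names(ms) <- sprintf("marker%02d", seq_len(n))
  ms
}

#' Assign read proportions for one target fraction
#'
#' Sets the target genome's read proportion to `target_prop` and splits the
#' remainder evenly across the contaminants.
#'
#' @param genomes list of [GenomeSpec-class] (exactly one target).
#' @param target_prop target read fraction in `[0, 1]`.
#' @return the updated genome list.
#' @export
setProportions <- function(genomes, target_prop) {
  roles <- vapply(genomes, function(g) g@role, "")
  if (sum(roles == "target") != 1L)
    stop("exactly one genome must have role 'target'", call. = FALSE)
  n_c <- sum(roles == "contaminant")
  for (i in seq_along(genomes)) {
    genomes[[i]]@readProportion <-
      if (roles[i] == "target") target_prop else (1 - target_prop) / n_c
  }
  genomes
}
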