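#' Label contigs with their source species
#'
#' Simulated mode (`truth` given): a contig's species is the majority
#' species among the reads aligned to it, ties going to the
#' lexicographically smallest species id; contigs with no aligned reads
#' are labelled `"UNKNOWN"`. Reference mode (`genomes` given): each contig
#' is aligned end-to-end against the reference genomes and labelled with
#' the best-matching genome at >= 95% identity, `"UNKNOWN"` otherwise.
#'
#' @param contigs a [ContigSet-class].
#' @param alignments read-to-contig table from [mapReads()] (simulated
#'   mode).
#' @param truth truth table (simulated mode).
#' @param genomes list of [GenomeSpec-class] reference genomes (reference
#'   mode).
#' @param min_identity identity floor for reference mode.
#' @return named character vector contig id -> species id.
#' @export
labelContigs <- function(contigs, alignments = NULL, truth = NULL,
                         genomes = NULL, min_identity = 0.95) {
  stopifnot(is(contigs, "ContigSet"))
  labels <- setNames(rep("UNKNOWN", length(contigs)),
                     names(contigs@sequences))
  if (!is.null(truth)) {
    if (is.null(alignments))
      stop("simulated-mode labelling needs the read alignments", call. = FALSE)
    sp <- setNames(truth$species_id, truth$read_id)
    al_sp <- sp[alignments$read_id]
    # majority species per contig, ties to the smallest species id
    tab <- table(alignments$contig_id, al_sp)
    if (nrow(tab) > 0L) {
      maj <- colnames(tab)[apply(tab, 1L, which.max)]  # which.max = first max
      labels[rownames(tab)] <- maj
    }
    return(labels)
  }
  if (is.null(genomes))
    stop("either truth or reference genomes must be supplied", call. = FALSE)
  refs <- new("ContigSet",
              sequences = .as_dss(
                vapply(genomes, function(g) as.character(g@sequence), ""),
                vapply(genomes, function(g) g@speciesId, "")),
              origin = rep("external", length(genomes)),
              sourceContig = vapply(genomes, function(g) g@speciesId, ""),
              coverage = matrix(numeric(0), 0L, 0L))
  fake_reads <- new("ReadSet",
                    sequences = contigs@sequences,
                    quality = Biostrings::PhredQuality(
                      strrep("I", Biostrings::width(contigs@sequences))),
                    mate = rep(0L, length(contigs)),
                    pairId = names(contigs@sequences))
  al <- mapReads(fake_reads, refs, min_identity = min_identity)
  labels[al$read_id] <- al$contig_id
  labels
}

#' Per-cluster purity
#'
#' For each cluster, the dominant species (DS) is the species contributing
#' the most contigs (ties broken by read count, then lexicographically).
#' Contig purity is the percentage of the cluster's contigs belonging to
#' the DS; read purity is the percentage of the cluster's reads whose
#' contig is labelled DS (reads inherit taxonomy from the contig they map
#' to). Purity tiers are cumulative: a 100%-pure cluster also counts in
#' the 90%+ and 80%+ tiers.
#'
#' @param assignment a [ClusterAssignment-class].
#' @param labels contig labels from [labelContigs()].
#' @param alignments read-to-contig table from [mapReads()].
#' @return data.frame with one row per cluster: `cluster`, `n_contigs`,
#'   `n_reads`, `dominant_species`, `purity_contig`, `purity_read`,
#'   `tier` (empty clusters get NA purities).
#' @export
clusterPurity <- function(assignment, labels, alignments) {
  stopifnot(is(assignment, "ClusterAssignment"))
  cl <- assignment@clusters
  read_cl <- cl[alignments$contig_id]
  read_lab <- labels[alignments$contig_id]
  out <- data.frame(cluster = seq_len(assignment@K), n_contigs = 0L,
                    n_reads = 0L, dominant_species = NA_character_,
                    purity_contig = NA_real_, purity_read = NA_real_,
                    tier = NA_character_, stringsAsFactors = FALSE)
  for (k in seq_len(assignment@K)) {
    members <- names(cl)[cl == k]
    out$n_contigs[k] <- length(members)
    in_k <- which(read_cl == k)
    out$n_reads[k] <- length(in_k)
    if (length(members) == 0L) next
    ctab <- table(labels[members])
    rtab <- table(factor(read_lab[in_k], levels = names(ctab)))
    # DS: most contigs, ties by most reads, then smallest species id
    ord <- order(-as.integer(ctab), -as.integer(rtab), names(ctab))
    ds <- names(ctab)[ord[1L]]
    out$dominant_species[k] <- ds
    out$purity_contig[k] <- 100 * ctab[[ds]] / length(members)
    out$purity_read[k] <- if (length(in_k))
      100 * sum(read_lab[in_k] == ds) / length(in_k) else NA_real_
    p <- out$purity_contig[k]
    out$tier[k] <- if (p == 100) "100" else if (p >= 90) "90+"
                   else if (p >= 80) "80+" else "below"
  }
  out
}

#' Cumulative purity tier counts
#'
#' How many clusters reach 100%, 90%+ and 80%+ purity (cumulative, so the
#' 90%+ tier includes the 100% clusters).
#'
#' @param purity data.frame from [clusterPurity()].
#' @param level `"contig"` or `"read"`: which purity column to summarise.
#' @return named integer vector with elements `"100"`, `"90+"`, `"80+"`.
#' @export
puritySummary <- function(purity, level = c("contig", "read")) {
  level <- match.arg(level)
  p <- purity[[paste0("purity_", level)]]
  p <- p[!is.na(p)]
  c("100" = sum(p == 100), "90+" = sum(p >= 90), "80+" = sum(p >= 80))
}

#' Target concentration across target clusters
#'
#' Truth-defined target clusters (TC) are clusters containing at least one
#' contig of the target species, independent of any marker call. Per TC,
#' the concentration is the percentage of all target-species contigs
#' (reads) in TCs that fall in this one; each level sums to 100 across
#' TCs. Reads are counted by their own truth label among the reads mapped
#' to the TC's contigs.
#'
#' @param assignment a [ClusterAssignment-class].
#' @param labels contig labels from [labelContigs()].
#' @param alignments read-to-contig table from [mapReads()].
#' @param truth truth table (defines the target species).
#' @return data.frame with one row per TC: `cluster`, `ts_contigs`,
#'   `concentration_contig`, `ts_reads`, `concentration_read`.
#' @export
targetConcentration <- function(assignment, labels, alignments, truth) {
  ts <- unique(truth$species_id[truth$role == "target"])
  if (length(ts) != 1L)
    stop("truth table must define exactly one target species", call. = FALSE)
  cl <- assignment@clusters
  ts_contig <- names(cl)[labels[names(cl)] == ts]
  if (length(ts_contig) == 0L)
    stop("no contig is labelled with the target species; truth misconfigured",
         call. = FALSE)
  tcs <- sort(unique(cl[ts_contig]))
  read_sp <- setNames(truth$species_id, truth$read_id)
  read_cl <- cl[alignments$contig_id]
  ts_read_cl <- read_cl[read_sp[alignments$read_id] == ts]
  n_contig <- vapply(tcs, function(k) sum(cl[ts_contig] == k), 0L)
  n_read <- vapply(tcs, function(k) sum(ts_read_cl == k, na.rm = TRUE), 0L)
  data.frame(cluster = tcs,
             ts_contigs = n_contig,
             concentration_contig = 100 * n_contig / sum(n_contig),
             ts_reads = n_read,
             concentration_read = if (sum(n_read) > 0)
               100 * n_read / sum(n_read) else rep(NA_real_, length(tcs)))
}

#' Sensitivity and specificity of the target/contamination dichotomy
#'
#' Against the marker-identified target clusters: true positives are
#' target-species contigs (reads) inside those clusters. Sensitivity
#' divides by all target items present at this stage (contigs in the
#' assignment labelled target; reads of the target species aligned to any
#' prepared contig), specificity by all items inside the identified
#' clusters. All four values are percentages of integer counts. When the
#' call is `NO_TARGET` all scores are 0 and `no_target` is set.
#'
#' @param call a [TargetCall-class].
#' @param assignment a [ClusterAssignment-class].
#' @param labels contig labels from [labelContigs()].
#' @param alignments read-to-contig table from [mapReads()].
#' @param truth truth table.
#' @return named numeric vector: `sensitivity_contig`,
#'   `specificity_contig`, `sensitivity_read`, `specificity_read` (in %),
#'   plus the underlying counts and a `no_target` flag (0/1).
#' @export
dichotomyScores <- function(call, assignment, labels, alignments, truth) {
  stopifnot(is(call, "TargetCall"))
  ts <- unique(truth$species_id[truth$role == "target"])
  if (length(ts) != 1L)
    stop("truth table must define exactly one target species", call. = FALSE)
  cl <- assignment@clusters
  all_target_contigs <- names(cl)[labels[names(cl)] == ts]
  read_sp <- setNames(truth$species_id, truth$read_id)
  al_is_target <- read_sp[alignments$read_id] == ts
  all_target_reads <- alignments$read_id[al_is_target]

  if (call@noTarget) {
    return(c(sensitivity_contig = 0, specificity_contig = 0,
             sensitivity_read = 0, specificity_read = 0,
             tp_contig = 0, called_contigs = 0,
             all_target_contigs = length(all_target_contigs),
             tp_read = 0, called_reads = 0,
             all_target_reads = length(all_target_reads),
             no_target = 1))
  }
  called <- call@targetContigs
  tp_contig <- sum(labels[called] == ts)
  in_call <- alignments$contig_id %in% called
  tp_read <- sum(in_call & al_is_target)
  called_reads <- sum(in_call)
  c(sensitivity_contig = 100 * tp_contig / length(all_target_contigs),
    specificity_contig = 100 * tp_contig / length(called),
    sensitivity_read = 100 * tp_read / length(all_target_reads),
    specificity_read = 100 * tp_read / called_reads,
    tp_contig = tp_contig, called_contigs = length(called),
    all_target_contigs = length(all_target_contigs),
    tp_read = tp_read, called_reads = called_reads,
    all_target_reads = length(all_target_reads),
    no_target = 0)
}

#' Base-level coverage of the target genome
#'
#' Maps the rescued reads back to the reference genome and measures the
#' union of covered intervals: `100 * mapped_bases / total_bases`.
#' Monotone non-decreasing in the rescued read set.
#'
#' @param reads rescued reads as a [ReadSet-class] (or any reads to
#'   assess).
#' @param genome a [GenomeSpec-class] or [Biostrings::DNAString].
#' @param min_identity mapping identity floor.
#' @return named numeric: `mapped_bases`, `total_bases`, `base_coverage`
#'   (%).
#' @export
baseCoverage <- function(reads, genome, min_identity = 0.95) {
  gseq <- if (is(genome, "GenomeSpec")) genome@sequence else genome
  ref <- new("ContigSet",
             sequences = .as_dss(as.character(gseq), "genome"),
             origin = "external", sourceContig = "genome",
             coverage = matrix(numeric(0), 0L, 0L))
  al <- mapReads(reads, ref, min_identity = min_identity)
  tb <- length(gseq)
  if (nrow(al) == 0L)
    return(c(mapped_bases = 0, total_bases = tb, base_coverage = 0))
  mb <- sum(IRanges::width(IRanges::reduce(
    IRanges::IRanges(start = al$start, end = al$end))))
  c(mapped_bases = mb, total_bases = tb, base_coverage = 100 * mb / tb)
}

#' Gene-level coverage of the target annotation
#'
#' Aligns the target contigs to the reference genome and counts a gene as
#' mapped when it overlaps any aligned contig interval by at least
#' `min_overlap` bp: `100 * mapped_genes / total_genes`.
#'
#' @param contigs target contigs as a [ContigSet-class].
#' @param genome a [GenomeSpec-class] or [Biostrings::DNAString].
#' @param annotation `GRanges` of gene intervals (e.g. from [readGenes()]
#'   or the simulator's planted annotation).
#' @param min_overlap minimum overlap in bp (default 1).
#' @param min_identity contig alignment identity floor.
#' @return named numeric: `mapped_genes`, `total_genes`, `gene_coverage`
#'   (%).
#' @export
geneCoverage <- function(contigs, genome, annotation, min_overlap = 1L,
                         min_identity = 0.95) {
  if (length(annotation) == 0L)
    stop("empty gene annotation", call. = FALSE)
  gseq <- if (is(genome, "GenomeSpec")) genome@sequence else genome
  ref <- new("ContigSet",
             sequences = .as_dss(as.character(gseq), "genome"),
             origin = "external", sourceContig = "genome",
             coverage = matrix(numeric(0), 0L, 0L))
  fake_reads <- new("ReadSet",
                    sequences = contigs@sequences,
                    quality = Biostrings::PhredQuality(
                      strrep("I", Biostrings::width(contigs@sequences))),
                    mate = rep(0L, length(contigs)),
                    pairId = names(contigs@sequences))
  al <- mapReads(fake_reads, ref, min_identity = min_identity)
  tg <- length(annotation)
  if (nrow(al) == 0L)
    return(c(mapped_genes = 0, total_genes = tg, gene_coverage = 0))
  covered <- IRanges::IRanges(start = al$start, end = al$end)
  mg <- sum(IRanges::countOverlaps(IRanges::ranges(annotation), covered,
                                   minoverlap = min_overlap) > 0L)
  c(mapped_genes = mg, total_genes = tg, gene_coverage = 100 * mg / tg)
}

#' Per-stage data loss
#'
#' Turns a stage ledger (rows of reads entering/surviving each stage, with
#' target-only counts when truth is known) into marginal and cumulative
#' loss percentages. Marginal survival fractions compose: their product
#' equals the cumulative survival at each stage.
#'
#' @param ledger data.frame with columns `stage`, `reads_in`, `reads_out`
#'   and optionally `target_in`, `target_out`.
#' @return data.frame with marginal and cumulative loss percentages per
#'   stage (total level and, when available, target level).
#' @export
dataLoss <- function(ledger) {
  stopifnot(all(c("stage", "reads_in", "reads_out") %in% names(ledger)))
  marg <- 100 * (1 - ledger$reads_out / ledger$reads_in)
  cum <- 100 * (1 - cumprod(ledger$reads_out / ledger$reads_in))
  out <- data.frame(stage = ledger$stage,
                    marginal_total = marg, cumulative_total = cum,
                    stringsAsFactors = FALSE)
  if (all(c("target_in", "target_out") %in% names(ledger))) {
    out$marginal_target <- 100 * (1 - ledger$target_out / ledger$target_in)
    out$cumulative_target <-
      100 * (1 - cumprod(ledger$target_out / ledger$target_in))
  }
  out
}
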