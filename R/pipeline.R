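#' Run the full screening pipeline
#'
#' Orchestrates the stages in order: quality trimming, unitig assembly (or
#' externally supplied contigs), contig length-window preparation, read
#' mapping and coverage, cluster-number estimation (or manual K), mixture
#' binning, marker-gene target calling and read rescue; when a truth table
#' is supplied, a full [EvaluationReport-class] is computed as well. A
#' `NO_TARGET` marker call short-circuits cleanly with `status = 2`.
#'
#' @param reads a [ReadSet-class] of raw reads.
#' @param markers named [Biostrings::DNAStringSet] of target marker genes.
#' @param K cluster count (integer or [SpeciesEstimate-class]); give
#'   either `K` or `rrnaRef`.
#' @param rrnaRef rRNA reference for [countSpecies()].
#' @param contigs optional externally assembled [ContigSet-class]
#'   (bypasses [buildUnitigs()]).
#' @param truth optional truth table enabling evaluation.
#' @param target_genome optional [GenomeSpec-class] for base/gene coverage
#'   evaluation.
#' @param annotation optional `GRanges` gene annotation for gene coverage.
#' @param trim a [trimParams()].
#' @param k,min_count assembler parameters.
#' @param min_len,max_len contig preparation window.
#' @param min_identity read-mapping identity floor.
#' @param evalue_cutoff,min_markers marker-calling parameters.
#' @param seed,n_init binning parameters.
#' @param out_dir optional output directory: target FASTQ, contig FASTA,
#'   report tables and a JSON run log are written there.
#' @return list with `status` (0 ok, 2 no target), `call`
#'   ([TargetCall-class]), `assignment`, `contigs` (prepared, with
#'   coverage), `alignments`, `ledger`, `report`
#'   ([EvaluationReport-class] or `NULL`), `config`.
#' @export
runPipeline <- function(reads, markers, K = NULL, rrnaRef = NULL,
                        contigs = NULL, truth = NULL, target_genome = NULL,
                        annotation = NULL, trim = trimParams(),
                        k = 31L, min_count = 2L,
                        min_len = 1000L, max_len = 10000L,
                        min_identity = 0.95, evalue_cutoff = 1e-20,
                        min_markers = 1L, seed = 1L, n_init = 10L,
                        out_dir = NULL) {
  stopifnot(is(reads, "ReadSet"))
  if (length(markers) == 0L)
    stop("pipeline config invalid: no marker genes supplied", call. = FALSE)
  if (is.null(K) && is.null(rrnaRef))
    stop("pipeline config invalid: give K or an rRNA reference", call. = FALSE)
  config <- list(trim = unclass(trim), k = k, min_count = min_count,
                 min_len = min_len, max_len = max_len,
                 min_identity = min_identity, evalue_cutoff = evalue_cutoff,
                 min_markers = min_markers, seed = seed, n_init = n_init,
                 K = if (is.null(K)) NA else
                   if (is(K, "SpeciesEstimate")) K@K else K)

  trimmed <- trimReads(reads, trim, truth = truth)
  ledger <- trimmed$ledger
  reads_t <- trimmed$reads

  raw_contigs <- if (is.null(contigs)) buildUnitigs(reads_t, k = k,
                                                    min_count = min_count)
                 else contigs

  # assembly-stage accounting: reads incorporated in (mappable to) the
  # assembled contigs before length filtering
  al_raw <- mapReads(reads_t, raw_contigs, min_identity = min_identity)
  ledger <- rbind(ledger, .stage_count("assembly", reads_t,
                                       unique(al_raw$read_id), ledger, truth))

  prep <- prepareContigs(raw_contigs, min_len = min_len, max_len = max_len)
  if (length(prep) == 0L)
    stop("pipeline stage 'prepare' produced no contigs", call. = FALSE)
  alignments <- mapReads(reads_t, prep, min_identity = min_identity)
  ledger <- rbind(ledger, .stage_count("binning", reads_t,
                                       unique(alignments$read_id), ledger, truth))
  prep <- computeCoverage(prep, alignments)

  est <- if (!is.null(K)) {
    if (is(K, "SpeciesEstimate")) K else overrideK(K)
  } else countSpecies(reads_t, rrnaRef)

  feats <- contigFeatures(prep)
  assignment <- fitClusters(feats, est@K, seed = seed, n_init = n_init)

  hits <- alignMarkers(markers, prep, evalue_cutoff = evalue_cutoff)
  call <- callTargetClusters(hits, assignment, min_markers = min_markers)
  if (call@noTarget) {
    return(list(status = 2L, call = call, assignment = assignment,
                contigs = prep, alignments = alignments, ledger = ledger,
                report = NULL, config = config))
  }
  call <- rescueReads(alignments, call, reads_t,
                      fastq_path = if (!is.null(out_dir)) {
                        dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
                        file.path(out_dir, "target_reads.fastq")
                      })
  ledger <- rbind(ledger, .stage_count("marker", reads_t, call@rescuedReads,
                                       ledger, truth))

  report <- NULL
  if (!is.null(truth)) {
    labels <- labelContigs(prep, alignments = alignments, truth = truth)
    purity <- clusterPurity(assignment, labels, alignments)
    conc <- targetConcentration(assignment, labels, alignments, truth)
    dich <- dichotomyScores(call, assignment, labels, alignments, truth)
    cov <- numeric(0)
    if (!is.null(target_genome)) {
      resc <- reads_t[which(names(reads_t@sequences) %in% call@rescuedReads)]
      cov <- baseCoverage(resc, target_genome, min_identity = min_identity)
      if (!is.null(annotation)) {
        tcs <- prep[which(names(prep@sequences) %in% call@targetContigs)]
        cov <- c(cov, geneCoverage(tcs, target_genome, annotation,
                                   min_identity = min_identity))
      }
    }
    report <- new("EvaluationReport", purity = purity, concentration = conc,
                  dichotomy = dich, coverage = cov,
                  dataLoss = dataLoss(ledger), ledger = ledger)
  }

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    Biostrings::writeXStringSet(
      prep@sequences[names(prep@sequences) %in% call@targetContigs],
      file.path(out_dir, "target_contigs.fasta"))
    if (!is.null(report)) writeReportTables(report, out_dir)
    log <- list(config = config,
                target_clusters = call@targetClusters,
                n_target_contigs = length(call@targetContigs),
                n_rescued_reads = length(call@rescuedReads),
                ledger = ledger)
    jsonlite::write_json(log, file.path(out_dir, "run_log.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  list(status = 0L, call = call, assignment = assignment, contigs = prep,
       alignments = alignments, ledger = ledger, report = report,
       config = config)
}

.stage_count <- function(stage, reads, surviving_ids, ledger, truth) {
  prev <- ledger[nrow(ledger), ]
  if (is.null(truth))
    return(.ledger_row(stage, prev$reads_out, length(surviving_ids)))
  tgt <- truth$read_id[truth$role == "target"]
  .ledger_row(stage, prev$reads_out, length(surviving_ids),
              prev$target_out, sum(surviving_ids %in% tgt))
}
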