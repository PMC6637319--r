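#' The gradient screening experiment
#'
#' Runs the package's standard benchmark: one planted-marker target genome
#' plus GC-separated contaminants ([communityPreset()]), simulated as
#' error-free 120 bp pairs at the given pool coverage for a gradient of
#' target read proportions (default 5/35/65/95%), each proportion screened
#' with the full pipeline ([runPipeline()]) at fixed K and evaluated
#' against the simulator's ground truth.
#'
#' @param seed integer seed driving every random choice (genomes, reads,
#'   binning restarts).
#' @param proportions target read fractions.
#' @param coverage fold coverage of the genome pool (default 50).
#' @param K cluster count passed to the binning stage (default 11: one
#'   target plus ten contaminants).
#' @param scale genome-size scale factor in (0, 1]: scales the preset's
#'   genome and annotation sizes down for quick runs.
#' @param bin_seed seed of the binning stage (default 42).
#' @param ... passed on to [communityPreset()].
#' @return list with `community` (the preset) and `runs`: per proportion,
#'   the [runPipeline()] result plus the simulated truth.
#' @export
gradientExperiment <- function(seed, proportions = c(0.05, 0.35, 0.65, 0.95),
                               coverage = 50, K = 11L, scale = 1,
                               bin_seed = 42L, ...) {
  stopifnot(scale > 0, scale <= 1)
  preset_args <- list(seed = seed, ...)
  if (scale < 1) {
    defaults <- list(target_length = 200000L, contaminant_length = 100000L,
                     n_genes = 50L)
    for (nm in names(defaults))
      if (is.null(preset_args[[nm]]))
        preset_args[[nm]] <- as.integer(round(defaults[[nm]] * scale))
    preset_args$n_genes <- max(preset_args$n_genes, 5L)
  }
  community <- do.call(communityPreset, preset_args)
  target <- community$genomes[[1L]]

  runs <- lapply(seq_along(proportions), function(i) {
    p <- proportions[i]
    genomes <- setProportions(community$genomes, p)
    sim <- simulateReads(genomes,
                         simConfig(coverage = coverage,
                                   seed = seed + 7L * i))
    res <- runPipeline(sim$reads, community$markers, K = K,
                       truth = sim$truth, target_genome = target,
                       annotation = community$annotation, seed = bin_seed)
    res$truth <- sim$truth
    res$proportion <- p
    res
  })
  names(runs) <- sprintf("target_%g%%", 100 * proportions)
  list(community = community, runs = runs)
}

#' Summarise a gradient experiment
#'
#' One row per target proportion with the headline evaluation quantities:
#' read/contig sensitivity and specificity, base and gene coverage, and
#' the cumulative target-read loss across the assembly and binning stages
#' (relative to the trimmed read set).
#'
#' @param experiment result of [gradientExperiment()].
#' @return data.frame, one row per proportion.
#' @export
summariseGradient <- function(experiment) {
  rows <- lapply(experiment$runs, function(run) {
    d <- run$report@dichotomy
    v <- run$report@coverage
    led <- run$ledger
    # target reads surviving assembly+binning vs entering assembly
    ab <- led[led$stage %in% c("assembly", "binning"), ]
    loss_ab <- 100 * (1 - ab$target_out[nrow(ab)] / ab$target_in[1L])
    data.frame(proportion = run$proportion,
               sensitivity_read = d[["sensitivity_read"]],
               specificity_read = d[["specificity_read"]],
               sensitivity_contig = d[["sensitivity_contig"]],
               specificity_contig = d[["specificity_contig"]],
               base_coverage = v[["base_coverage"]],
               gene_coverage = v[["gene_coverage"]],
               loss_assembly_binning = loss_ab)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
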