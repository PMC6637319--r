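# Evaluation formulas against naive counting oracles

# A small hand-built world: 2 species, 5 contigs, reads inheriting labels.
make_eval_world <- function() {
  cl <- setNames(c(1L, 1L, 1L, 2L, 2L), sprintf("ctg%05d", 1:5))
  asg <- new("ClusterAssignment", K = 2L, clusters = cl,
             responsibilities = matrix(1, 5L, 2L), seed = 1L)
  labels <- setNames(c("tgt", "tgt", "con", "con", "con"), names(cl))
  # reads: 10 per contig from the labelled species, plus 2 strays
  al <- data.frame(
    read_id = sprintf("r%03d", 1:52),
    contig_id = c(rep(names(cl), each = 10L), "ctg00001", "ctg00004"),
    start = 1L, end = 100L, stringsAsFactors = FALSE)
  sp <- c(rep(c("tgt", "tgt", "con", "con", "con"), each = 10L), "con", "tgt")
  truth <- data.frame(read_id = al$read_id, species_id = sp,
                      role = ifelse(sp == "tgt", "target", "contaminant"))
  list(asg = asg, labels = labels, al = al, truth = truth)
}

test_that("contig labels follow the majority of their reads", {
  w <- make_eval_world()
  ctg <- make_contigs(vapply(1:5, function(i) random_seq(1000L, i), ""),
                      ids = sprintf("ctg%05d", 1:5))
  labs <- labelContigs(ctg, alignments = w$al, truth = w$truth)
  # ctg00001 has 10 tgt + 1 con reads -> tgt; ctg00004 has 10 con + 1 tgt
  expect_equal(unname(labs["ctg00001"]), "tgt")
  expect_equal(unname(labs["ctg00004"]), "con")
  # chimeric 60/40 majority rule
  al2 <- data.frame(read_id = sprintf("x%02d", 1:10),
                    contig_id = "ctg00002", start = 1L, end = 10L)
  tr2 <- data.frame(read_id = al2$read_id,
                    species_id = c(rep("X", 6), rep("Y", 4)),
                    role = c(rep("target", 6), rep("contaminant", 4)))
  labs2 <- labelContigs(ctg, alignments = al2, truth = tr2)
  expect_equal(unname(labs2["ctg00002"]), "X")
  expect_equal(unname(labs2["ctg00003"]), "UNKNOWN")  # no reads
  expect_error(labelContigs(ctg), "truth or reference")
})

test_that("reference-mode labels match genome of origin on clean simulations", {
  comm <- communityPreset(seed = 2L, n_contaminants = 2L,
                          target_length = 20000L,
                          contaminant_length = 15000L,
                          n_markers = 1L, n_genes = 2L)
  pieces <- lapply(comm$genomes, function(g)
    substring(as.character(g@sequence), c(1L, 5001L), c(5000L, 10000L)))
  ctg <- make_contigs(unlist(pieces), ids = sprintf("c%02d", 1:6))
  labs <- labelContigs(ctg, genomes = comm$genomes)
  want <- rep(vapply(comm$genomes, function(g) g@speciesId, ""), each = 2L)
  expect_equal(unname(labs), want)
})

test_that("purity matches the naive recount and tiers are cumulative", {
  w <- make_eval_world()
  pur <- clusterPurity(w$asg, w$labels, w$al)
  # cluster 1: contigs tgt,tgt,con -> DS tgt, purity 2/3
  expect_equal(pur$dominant_species[1], "tgt")
  expect_equal(pur$purity_contig[1], 100 * 2 / 3)
  # reads in cluster 1: 31, of which labelled tgt = 21 (10+10+1 on tgt contigs)
  expect_equal(pur$n_reads[1], 31L)
  expect_equal(pur$purity_read[1], 100 * 21 / 31)
  # cluster 2 all-con
  expect_equal(pur$purity_contig[2], 100)
  expect_equal(pur$tier[2], "100")
  # tier summary on constructed purities {100, 95, 85, 70}
  fake <- data.frame(purity_contig = c(100, 95, 85, 70),
                     purity_read = c(100, 95, 85, 70))
  expect_equal(puritySummary(fake, "contig"),
               c("100" = 1L, "90+" = 2L, "80+" = 3L))
  # empty cluster row is NA, not an error
  asg3 <- new("ClusterAssignment", K = 3L, clusters = w$asg@clusters,
              responsibilities = matrix(1, 5L, 3L), seed = 1L)
  pur3 <- clusterPurity(asg3, w$labels, w$al)
  expect_true(is.na(pur3$purity_contig[3]))
})

test_that("target concentration is normalised over truth-defined TCs", {
  w <- make_eval_world()
  conc <- targetConcentration(w$asg, w$labels, w$al, w$truth)
  # tgt-labelled contigs live only in cluster 1 -> a single TC at 100%
  expect_equal(conc$cluster, 1L)
  expect_equal(conc$concentration_contig, 100)
  expect_equal(sum(conc$concentration_contig), 100, tolerance = 1e-9)
  expect_equal(sum(conc$concentration_read), 100, tolerance = 1e-9)
  # 94/6 split across two clusters
  cl <- setNames(rep(1:2, c(94L, 6L)), sprintf("t%03d", 1:100))
  asg <- new("ClusterAssignment", K = 2L, clusters = cl,
             responsibilities = matrix(1, 100L, 2L), seed = 1L)
  labels <- setNames(rep("tgt", 100L), names(cl))
  al <- data.frame(read_id = sprintf("r%03d", 1:100), contig_id = names(cl),
                   start = 1L, end = 10L)
  truth <- data.frame(read_id = al$read_id, species_id = "tgt",
                      role = "target")
  conc2 <- targetConcentration(asg, labels, al, truth)
  expect_equal(conc2$concentration_contig, c(94, 6))
})

test_that("sensitivity and specificity equal the confusion-matrix oracle", {
  w <- make_eval_world()
  call <- new("TargetCall", targetClusters = 1L,
              targetContigs = names(w$asg@clusters)[w$asg@clusters == 1L],
              rescuedReads = character(0), markerTally = data.frame(),
              noTarget = FALSE)
  d <- dichotomyScores(call, w$asg, w$labels, w$al, w$truth)
  # oracle by direct recount
  called_contigs <- sprintf("ctg%05d", 1:3)
  tp_c <- sum(w$labels[called_contigs] == "tgt")           # 2
  all_tc <- sum(w$labels == "tgt")                         # 2
  expect_equal(unname(d["sensitivity_contig"]), 100 * tp_c / all_tc)
  expect_equal(unname(d["specificity_contig"]), 100 * tp_c / 3)
  in_call <- w$al$contig_id %in% called_contigs
  is_t <- w$truth$species_id[match(w$al$read_id, w$truth$read_id)] == "tgt"
  expect_equal(unname(d["sensitivity_read"]),
               100 * sum(in_call & is_t) / sum(is_t))
  expect_equal(unname(d["specificity_read"]),
               100 * sum(in_call & is_t) / sum(in_call))
  # worked example: TCs hold 90 target + 5 contaminant contigs of 100 total
  cl <- setNames(rep(1:2, c(95L, 15L)), sprintf("c%03d", 1:110))
  labels <- setNames(c(rep("t", 90), rep("c", 5), rep("t", 10), rep("c", 5)),
                     names(cl))
  asg <- new("ClusterAssignment", K = 2L, clusters = cl,
             responsibilities = matrix(1, 110L, 2L), seed = 1L)
  call2 <- new("TargetCall", targetClusters = 1L,
               targetContigs = names(cl)[cl == 1L],
               rescuedReads = character(0), markerTally = data.frame(),
               noTarget = FALSE)
  al0 <- data.frame(read_id = character(), contig_id = character(),
                    start = integer(), end = integer())
  tr0 <- data.frame(read_id = "z", species_id = "t", role = "target")
  d2 <- dichotomyScores(call2, asg, labels, al0, tr0)
  expect_equal(unname(d2["sensitivity_contig"]), 90)
  expect_equal(unname(d2["specificity_contig"]), 100 * 90 / 95,
               tolerance = 1e-9)
  # NO_TARGET zeroes the scores and flags it
  none <- new("TargetCall", targetClusters = integer(0),
              targetContigs = character(0), rescuedReads = character(0),
              markerTally = data.frame(), noTarget = TRUE)
  d0 <- dichotomyScores(none, w$asg, w$labels, w$al, w$truth)
  expect_equal(unname(d0["sensitivity_read"]), 0)
  expect_equal(unname(d0["no_target"]), 1)
})

test_that("base coverage equals a per-base bitmap on the genome", {
  g <- makeRandomGenome(1000L, 0.5, seed = 60L)
  gseq <- as.character(g@sequence)
  # one 120 bp read -> 12.0%
  one <- make_reads(substring(gseq, 101L, 220L))
  bc <- baseCoverage(one, g)
  expect_equal(unname(bc["base_coverage"]), 12)
  # tiling reads -> 100%
  full <- tile_reads(gseq, read_len = 100L, stride = 50L)
  expect_equal(unname(baseCoverage(full, g)["base_coverage"]), 100)
  # random placements vs brute-force bitmap
  set.seed(61)
  starts <- sample.int(880L, 30L)
  rs <- make_reads(substring(gseq, starts, starts + 119L),
                   ids = sprintf("b%03d", 1:30))
  bitmap <- logical(1000L)
  for (s in starts) bitmap[s:(s + 119L)] <- TRUE
  got <- baseCoverage(rs, g)
  expect_equal(unname(got["mapped_bases"]), sum(bitmap))
  # monotone in the read set
  less <- baseCoverage(rs[1:10], g)
  expect_lte(less[["mapped_bases"]], got[["mapped_bases"]])
})

test_that("gene coverage counts genes overlapped by contig alignments", {
  g <- makeRandomGenome(20000L, 0.5, seed = 70L)
  g <- plantGenes(g, n = 20L, gene_length = 400L, seed = 71L)
  gseq <- as.character(g@sequence)
  # contigs tiling everything -> all 20 genes found
  ctg <- make_contigs(substring(gseq, c(1, 8001, 15001), c(8000, 15000, 20000)))
  gc_all <- geneCoverage(ctg, g, g@genes)
  expect_equal(unname(gc_all["gene_coverage"]), 100)
  expect_equal(unname(gc_all["total_genes"]), 20)
  # a contig missing a gene entirely leaves it uncovered
  gene1 <- g@genes[1]
  before <- IRanges::start(gene1) - 1L
  if (before > 1000L) {
    ctg2 <- make_contigs(substring(gseq, 1L, before))
    gc2 <- geneCoverage(ctg2, g, g@genes)
    expect_lt(gc2[["mapped_genes"]], 20)
    # oracle: genes overlapping [1, before] by >= 1 bp
    want <- sum(IRanges::start(g@genes) <= before)
    expect_equal(unname(gc2["mapped_genes"]), want)
  }
  expect_error(geneCoverage(ctg, g, GenomicRanges::GRanges()), "empty")
})

test_that("stage losses compose multiplicatively", {
  led <- data.frame(stage = c("trim", "assembly", "binning", "marker"),
                    reads_in = c(1000L, 990L, 980L, 950L),
                    reads_out = c(990L, 980L, 950L, 900L),
                    target_in = c(400L, 398L, 396L, 390L),
                    target_out = c(398L, 396L, 390L, 380L))
  dl <- dataLoss(led)
  expect_equal(dl$marginal_total, 100 * (1 - led$reads_out / led$reads_in))
  surv <- cumprod(led$target_out / led$target_in)
  expect_equal(dl$cumulative_target, 100 * (1 - surv))
  # no loss anywhere -> all zeros
  led0 <- data.frame(stage = "trim", reads_in = 10L, reads_out = 10L)
  expect_equal(dataLoss(led0)$cumulative_total, 0)
  # 100 in, 95 out -> 5%
  led5 <- data.frame(stage = "all", reads_in = 100L, reads_out = 95L)
  expect_equal(dataLoss(led5)$marginal_total, 5)
})
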