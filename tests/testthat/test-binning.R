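# Composition+coverage features and Gaussian-mixture binning

test_that("tetranucleotide features canonicalise and normalise", {
  ctg <- make_contigs(c(strrep("A", 2000L), random_seq(2000L, 1)))
  al <- data.frame(read_id = character(), contig_id = character(),
                   start = integer(), end = integer())
  ctg <- computeCoverage(ctg, al)
  feats <- contigFeatures(ctg)
  freq <- attr(feats, "frequencies")
  # pre-log frequencies sum to 1
  expect_equal(unname(rowSums(freq)), c(1, 1), tolerance = 1e-9)
  expect_equal(ncol(freq), 136L)
  # poly-A contig: all unsmoothed mass on the canonical AAAA/TTTT class
  counts_a <- Biostrings::oligonucleotideFrequency(
    contigSequences(ctg)[1], 4L)
  expect_equal(sum(counts_a) , counts_a[1, "AAAA"][[1]])

  # a contig and its reverse complement featurise identically
  s <- random_seq(3000L, seed = 2L)
  pair <- computeCoverage(make_contigs(c(s, revcomp(s))), al)
  fr <- attr(contigFeatures(pair), "frequencies")
  expect_equal(fr[1, ], fr[2, ], tolerance = 1e-12)
})

test_that("composition-separated genomes are recovered exactly (ARI 1)", {
  frag <- function(seq, n, len, ids) {
    starts <- round(seq(1, nchar(seq) - len, length.out = n))
    make_contigs(substring(seq, starts, starts + len - 1L), ids = ids)
  }
  gA <- random_seq(60000L, seed = 1L, gc = 0.30)
  gB <- random_seq(60000L, seed = 2L, gc = 0.70)
  ctg <- make_contigs(
    c(substring(gA, seq(1, 55001, by = 5000), seq(1, 55001, by = 5000) + 4999L),
      substring(gB, seq(1, 55001, by = 5000), seq(1, 55001, by = 5000) + 4999L)),
    ids = sprintf("c%03d", 1:24))
  truth_lab <- rep(c(1L, 2L), each = 12L)
  ctg <- computeCoverage(ctg, data.frame(read_id = character(),
                                         contig_id = character(),
                                         start = integer(), end = integer()))
  feats <- contigFeatures(ctg)
  asg <- fitClusters(feats, K = 2L, seed = 1L)
  expect_equal(mclust::adjustedRandIndex(clusterLabels(asg), truth_lab), 1)
})

test_that("identical composition is separated by the coverage feature", {
  base <- random_seq(60000L, seed = 5L)
  pieces <- substring(base, seq(1, 55001, by = 5000), seq(1, 55001, by = 5000) + 4999L)
  ctg <- make_contigs(c(pieces, pieces), ids = sprintf("c%03d", 1:24))
  # same sequences, 10X vs 100X depth
  depth <- c(rep(10, 12), rep(100, 12))
  al <- do.call(rbind, lapply(seq_len(24), function(i) {
    n <- round(depth[i] * 5000 / 100)
    data.frame(read_id = sprintf("r%03d_%04d", i, seq_len(n)),
               contig_id = sprintf("c%03d", i),
               start = 1L, end = 100L)
  }))
  # computeCoverage uses aligned bases / length; emulate depth directly
  al$end <- 100L
  ctg <- computeCoverage(ctg, al)
  expect_equal(unname(contigCoverage(ctg)[1, 1]), 10, tolerance = 0.01)
  asg <- fitClusters(contigFeatures(ctg), K = 2L, seed = 1L)
  truth_lab <- rep(c(1L, 2L), each = 12L)
  expect_gte(mclust::adjustedRandIndex(clusterLabels(asg), truth_lab), 0.95)
})

test_that("binning is deterministic and label-invariant under permutation", {
  gA <- random_seq(40000L, seed = 11L, gc = 0.35)
  gB <- random_seq(40000L, seed = 12L, gc = 0.65)
  ctg <- make_contigs(
    c(substring(gA, seq(1, 36001, by = 4000), seq(1, 36001, by = 4000) + 3999L),
      substring(gB, seq(1, 36001, by = 4000), seq(1, 36001, by = 4000) + 3999L)),
    ids = sprintf("c%03d", 1:20))
  ctg <- computeCoverage(ctg, data.frame(read_id = character(),
                                         contig_id = character(),
                                         start = integer(), end = integer()))
  feats <- contigFeatures(ctg)
  a1 <- fitClusters(feats, K = 2L, seed = 7L)
  a2 <- fitClusters(feats, K = 2L, seed = 7L)
  expect_identical(clusterLabels(a1), clusterLabels(a2))
  # permuting rows permutes only the labels, not the partition
  perm <- c(20:1)
  a3 <- fitClusters(feats[perm, ], K = 2L, seed = 7L)
  expect_equal(mclust::adjustedRandIndex(
    clusterLabels(a1), clusterLabels(a3)[names(clusterLabels(a1))]), 1)
})

test_that("mixture fit agrees with an independent model-based clustering", {
  gA <- random_seq(50000L, seed = 21L, gc = 0.30)
  gB <- random_seq(50000L, seed = 22L, gc = 0.60)
  ctg <- make_contigs(
    c(substring(gA, seq(1, 45001, by = 5000), seq(1, 45001, by = 5000) + 4999L),
      substring(gB, seq(1, 45001, by = 5000), seq(1, 45001, by = 5000) + 4999L)),
    ids = sprintf("c%03d", 1:20))
  ctg <- computeCoverage(ctg, data.frame(read_id = character(),
                                         contig_id = character(),
                                         start = integer(), end = integer()))
  feats <- contigFeatures(ctg)
  ours <- clusterLabels(fitClusters(feats, K = 2L, seed = 3L))
  withr::local_package("mclust")
  # independent route: diagonal-model clustering of the leading PCs
  pca <- prcomp(feats)
  mc <- mclust::Mclust(pca$x[, 1:3], G = 2, modelNames = "VVI",
                       verbose = FALSE)
  expect_equal(mclust::adjustedRandIndex(ours, mc$classification), 1)
})

test_that("K = 1 trivially groups everything; K > n errors; report covers empties", {
  ctg <- make_contigs(vapply(1:5, function(i) random_seq(2000L, i), ""))
  ctg <- computeCoverage(ctg, data.frame(read_id = character(),
                                         contig_id = character(),
                                         start = integer(), end = integer()))
  feats <- contigFeatures(ctg)
  asg1 <- fitClusters(feats, K = 1L, seed = 1L)
  expect_true(all(clusterLabels(asg1) == 1L))
  expect_error(fitClusters(feats, K = 6L, seed = 1L), "reduce K")
  asg3 <- fitClusters(feats, K = 3L, seed = 1L)
  rep3 <- clusterReport(asg3, ctg)
  expect_equal(nrow(rep3), 3L)
  expect_equal(sum(rep3$n_contigs), 5L)  # column sums equal contig count
  expect_equal(sum(rep3$total_bases), 5 * 2000)
})
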