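# Built-in unitig assembler, contig preparation, coverage, stats

test_that("error-free tiling reads assemble into the single source sequence", {
  src <- random_seq(5000L, seed = 10L)
  rs <- tile_reads(src, read_len = 60L, stride = 2L)
  ctg <- buildUnitigs(rs, k = 31L, min_count = 1L)
  expect_equal(length(ctg), 1L)
  got <- as.character(contigSequences(ctg)[[1]])
  expect_true(got == src || got == revcomp(src))
  # with the abundance filter on, only the singleton terminal k-mers of the
  # tiling can be shaved off; the unitig still covers the source interior
  ctg2 <- buildUnitigs(rs, k = 31L, min_count = 2L)
  expect_equal(length(ctg2), 1L)
  got2 <- as.character(contigSequences(ctg2)[[1]])
  expect_gte(nchar(got2), 4990L)
  expect_true(grepl(got2, src, fixed = TRUE) ||
                grepl(got2, revcomp(src), fixed = TRUE))
})

test_that("empty input yields an empty assembly with a warning", {
  rs <- make_reads(character(0), ids = character(0))
  expect_equal(length(suppressWarnings(buildUnitigs(rs))), 0L)
  rs1 <- make_reads("ACGTACGTACGTACGTACGTACGTACGTACGTACGT")
  expect_warning(ctg <- buildUnitigs(rs1, k = 31L, min_count = 5L),
                 "no k-mer")
  expect_equal(length(ctg), 0L)
})

test_that("unitigs equal brute-force non-branching-path enumeration", {
  # a genome with one exact 200 bp repeat forces branching
  set.seed(77)
  rep_unit <- random_seq(200L, seed = 300L)
  parts <- c(random_seq(1200L, seed = 301L), rep_unit,
             random_seq(900L, seed = 302L), rep_unit,
             random_seq(1100L, seed = 303L))
  src <- paste(parts, collapse = "")
  rs <- tile_reads(src, read_len = 60L, stride = 1L)
  ctg <- buildUnitigs(rs, k = 31L, min_count = 1L)
  expect_gte(length(ctg), 3L)
  got <- unname(sort(as.character(contigSequences(ctg))))
  want <- oracle_unitigs(as.character(readSequences(rs)), k = 31L)
  expect_identical(got, want)

  # repeat-free case agrees too
  src2 <- random_seq(800L, seed = 400L)
  rs2 <- tile_reads(src2, read_len = 50L, stride = 1L)
  ctg2 <- buildUnitigs(rs2, k = 21L, min_count = 1L)
  got2 <- unname(sort(as.character(contigSequences(ctg2))))
  expect_identical(got2, oracle_unitigs(as.character(readSequences(rs2)),
                                        k = 21L))
})

test_that("assembly is invariant under reverse-complementing the reads", {
  src <- random_seq(3000L, seed = 12L)
  rs <- tile_reads(src, read_len = 60L, stride = 2L)
  rc <- make_reads(revcomp(as.character(readSequences(rs))),
                   ids = names(readSequences(rs)))
  a <- unname(sort(as.character(contigSequences(buildUnitigs(rs, min_count = 1L)))))
  b <- unname(sort(as.character(contigSequences(buildUnitigs(rc, min_count = 1L)))))
  expect_identical(a, b)
})

test_that("unitigs are substrings of the source genome for error-free input", {
  src <- random_seq(4000L, seed = 13L)
  rs <- tile_reads(src, read_len = 55L, stride = 3L)
  ctg <- buildUnitigs(rs, k = 31L, min_count = 1L)
  both <- paste0(src, "NNN", revcomp(src))
  for (s in as.character(contigSequences(ctg)))
    expect_true(grepl(s, both, fixed = TRUE))
})

test_that("contig preparation applies the length window with tail merging", {
  ctg <- make_contigs(c(random_seq(25000L, 1), random_seq(10500L, 2),
                        random_seq(800L, 3), random_seq(4000L, 4)))
  prep <- prepareContigs(ctg)
  w <- setNames(Biostrings::width(contigSequences(prep)),
                sourceContigs(prep))
  expect_equal(unname(w[sourceContigs(prep) == "ctg00001"]),
               c(10000L, 10000L, 5000L))
  expect_equal(unname(w[sourceContigs(prep) == "ctg00002"]), 10500L)
  expect_false("ctg00003" %in% sourceContigs(prep))
  expect_equal(unname(w[sourceContigs(prep) == "ctg00004"]), 4000L)
  # base conservation over inputs that passed the floor
  expect_equal(sum(Biostrings::width(contigSequences(prep))),
               25000L + 10500L + 4000L)
  # fragments reassemble to their parent
  pieces <- prep[which(sourceContigs(prep) == "ctg00001")]
  expect_identical(paste(as.character(contigSequences(pieces)), collapse = ""),
                   as.character(contigSequences(ctg)[[1]]))
})

test_that("coverage is mean per-base depth and scales linearly in the reads", {
  src <- random_seq(5000L, seed = 20L)
  ctg <- make_contigs(src)
  starts <- seq(1L, 4901L, length.out = 500L)
  rs <- make_reads(substring(src, starts, starts + 99L),
                   ids = sprintf("c%04d", seq_along(starts)))
  al <- mapReads(rs, ctg)
  cov1 <- unname(contigCoverage(computeCoverage(ctg, al))[1, 1])
  expect_equal(cov1, 500 * 100 / 5000, tolerance = 0.01)  # ~10X
  al2 <- rbind(al, transform(al, read_id = paste0(read_id, "b")))
  cov2 <- unname(contigCoverage(computeCoverage(ctg, al2))[1, 1])
  expect_equal(cov2, 2 * cov1)
  # no reads -> zero
  cov0 <- unname(contigCoverage(computeCoverage(ctg, al[0, ]))[1, 1])
  expect_equal(cov0, 0)
})

test_that("N50 follows the cumulative-length definition", {
  ctg <- make_contigs(vapply(c(10L, 8L, 6L, 4L, 2L) * 300L,
                             function(n) random_seq(n, seed = n), ""))
  # scale: lengths 3000,2400,1800,1200,600; total 9000; 3000+2400 >= 4500
  expect_equal(assemblyStats(ctg)$n50, 2400L)
  one <- make_contigs(random_seq(1234L, 5))
  expect_equal(assemblyStats(one)$n50, 1234L)
  expect_equal(assemblyStats(one)$mean_length, 1234)
  eq <- make_contigs(vapply(1:4, function(i) random_seq(1500L, i), ""))
  expect_equal(assemblyStats(eq)$n50, 1500L)
  expect_error(assemblyStats(make_contigs(character(0), ids = character(0))),
               "empty")
})

test_that("external contigs join the pipeline after preparation", {
  fa <- withr::local_tempfile(fileext = ".fasta")
  seqs <- Biostrings::DNAStringSet(c(a = random_seq(2000L, 1),
                                     b = random_seq(1500L, 2)))
  Biostrings::writeXStringSet(seqs, fa)
  ctg <- externalContigs(fa)
  expect_equal(contigIDs(ctg), c("a", "b"))
  expect_true(all(contigOrigin(ctg) == "external"))
  expect_equal(length(prepareContigs(ctg, min_len = 1600L)), 1L)
})
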