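# Marker alignment, target-cluster calling, read mapping and rescue

test_that("a planted marker is found at identity 1 over its full length", {
  marker <- Biostrings::DNAStringSet(c(ftsZ = random_seq(600L, seed = 1L)))
  host <- paste0(random_seq(2000L, 2L), as.character(marker[[1L]]),
                 random_seq(2000L, 3L))
  ctg <- make_contigs(c(host, random_seq(3000L, 4L)))
  hits <- alignMarkers(marker, ctg)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$contig_id, "ctg00001")
  expect_equal(hits$identity, 1)
  expect_equal(hits$length, 600L)
  expect_lt(hits$evalue, 1e-20)
  # reverse-complement planting is found on the minus strand
  host_rc <- paste0(random_seq(1500L, 5L), revcomp(as.character(marker[[1L]])),
                    random_seq(1500L, 6L))
  hits_rc <- alignMarkers(marker, make_contigs(host_rc))
  expect_equal(nrow(hits_rc), 1L)
  expect_equal(hits_rc$strand, "-")
  expect_equal(hits_rc$identity, 1)
})

test_that("contigs sharing no 15-mer with a marker yield zero hits", {
  marker <- Biostrings::DNAStringSet(c(m = random_seq(300L, seed = 9L)))
  ctg_seq <- random_seq(5000L, seed = 10L)
  # exhaustive oracle: verify the premise before asserting the conclusion
  m <- as.character(marker[[1L]])
  wins <- substring(m, 1:(nchar(m) - 14L), 15:nchar(m))
  shared <- any(vapply(c(wins, revcomp(wins)),
                       function(w) grepl(w, ctg_seq, fixed = TRUE), TRUE))
  expect_false(shared)
  expect_equal(nrow(alignMarkers(marker, make_contigs(ctg_seq))), 0L)
})

test_that("short chance matches fail the e-value cutoff", {
  # plant only a 20 bp fragment of the marker: perfect but insignificant
  marker <- Biostrings::DNAStringSet(c(m = random_seq(300L, seed = 20L)))
  frag <- substring(as.character(marker[[1L]]), 1L, 20L)
  ctg <- make_contigs(paste0(random_seq(2000L, 21L), frag,
                             random_seq(2000L, 22L)))
  hits_all <- alignMarkers(marker, ctg, evalue_cutoff = Inf)
  expect_gte(nrow(hits_all), 1L)
  best <- hits_all[which.min(hits_all$evalue), ]
  # significance-formula oracle: E = K m n exp(-lambda S)
  lambda <- uniroot(function(l) 0.25 * exp(l) + 0.75 * exp(-2 * l) - 1,
                    c(1e-6, 10), tol = 1e-12)$root
  n_total <- sum(Biostrings::width(contigSequences(ctg)))
  expect_equal(best$evalue, 0.621 * 300 * n_total * exp(-lambda * best$score),
               tolerance = 1e-9)
  expect_gt(best$evalue, 1e-20)
  expect_equal(nrow(alignMarkers(marker, ctg)), 0L)  # rejected at default cutoff
})

test_that("external tabular hits are parsed and filtered at the same cutoff", {
  tab <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("m1\tctg00001\t100.00\t600\t0\t0\t1\t600\t10\t609\t1e-180\t1100",
               "m2\tctg00002\t95.00\t40\t2\t0\t1\t40\t50\t11\t1e-05\t38"), tab)
  hits <- alignMarkers(Biostrings::DNAStringSet(), make_contigs("ACGT"),
                       hits_file = tab)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$marker_id, "m1")
  expect_equal(hits$strand, "+")
})

test_that("clusters are called by distinct-marker count with monotone min_markers", {
  asg <- new("ClusterAssignment", K = 4L,
             clusters = setNames(c(1L, 1L, 2L, 3L, 4L),
                                 sprintf("ctg%05d", 1:5)),
             responsibilities = matrix(1, 5L, 4L), seed = 1L)
  hits <- data.frame(marker_id = c("a", "b", "a", "a"),
                     contig_id = c("ctg00001", "ctg00002", "ctg00003",
                                   "ctg00003"))
  call1 <- callTargetClusters(hits, asg, min_markers = 1L)
  expect_equal(targetClusters(call1), c(1L, 2L))
  expect_setequal(targetContigs(call1), sprintf("ctg%05d", 1:3))
  call2 <- callTargetClusters(hits, asg, min_markers = 2L)
  expect_equal(targetClusters(call2), 1L)  # raising the bar only shrinks
  # multiple clusters can be target simultaneously
  hits3 <- data.frame(marker_id = "a",
                      contig_id = c("ctg00001", "ctg00003", "ctg00004"))
  expect_equal(targetClusters(callTargetClusters(hits3, asg)), c(1L, 2L, 3L))
  # no hits -> NO_TARGET, not an error
  expect_message(none <- callTargetClusters(hits[0, ], asg), "NO_TARGET")
  expect_true(isNoTarget(none))
})

test_that("read mapping is exact for substrings, tie-broken by contig id", {
  src <- random_seq(4000L, seed = 30L)
  ctg <- make_contigs(c(src, random_seq(4000L, 31L)))
  rs <- make_reads(c(substring(src, 101L, 220L),
                     revcomp(substring(src, 1001L, 1120L)),
                     random_seq(120L, seed = 32L)),
                   ids = c("fwd", "rev", "noise"))
  al <- mapReads(rs, ctg)
  expect_equal(nrow(al), 2L)  # noise read shares no 21-mer: unassigned
  fwd <- al[al$read_id == "fwd", ]
  expect_equal(fwd$contig_id, "ctg00001")
  expect_equal(fwd$start, 101L)
  expect_equal(fwd$identity, 1)
  expect_equal(fwd$strand, "+")
  rev <- al[al$read_id == "rev", ]
  expect_equal(rev$start, 1001L)
  expect_equal(rev$strand, "-")
  # seed-intersection oracle for the unassigned read
  noise <- as.character(readSequences(rs)[["noise"]])
  wins <- substring(noise, 1:100, 21:120)
  expect_false(any(vapply(c(wins, revcomp(wins)), function(w)
    grepl(w, src, fixed = TRUE) ||
      grepl(w, as.character(contigSequences(ctg)[[2]]), fixed = TRUE), TRUE)))
  # identical contigs: lowest contig id wins
  twin <- make_contigs(c(src, src), ids = c("b_ctg", "a_ctg"))
  al2 <- mapReads(rs[1], twin)
  expect_equal(al2$contig_id, "a_ctg")
})

test_that("rescue takes reads on target contigs and mate-rescues pairs", {
  src <- random_seq(6000L, seed = 40L)
  other <- random_seq(6000L, seed = 41L)
  ctg <- make_contigs(c(src, other))
  rs <- make_reads(c(substring(src, 1, 120), revcomp(substring(src, 181, 300)),
                     substring(other, 1, 120), random_seq(120L, 42L)),
                   ids = c("p1/1", "p1/2", "p2/1", "p2/2"),
                   mate = c(1L, 2L, 1L, 2L),
                   pair_id = c("p1", "p1", "p2", "p2"))
  al <- mapReads(rs, ctg)
  asg <- new("ClusterAssignment", K = 2L,
             clusters = setNames(1:2, contigIDs(ctg)),
             responsibilities = matrix(1, 2L, 2L), seed = 1L)
  hits <- data.frame(marker_id = "m", contig_id = "ctg00001")
  call <- callTargetClusters(hits, asg)
  call <- rescueReads(al, call, rs)
  expect_setequal(rescuedReads(call), c("p1/1", "p1/2"))
  # rescued reads are a subset of mapped reads
  expect_true(all(rescuedReads(call) %in% al$read_id))

  # mate rescue: p2/1 on target, p2/2 unmapped -> both emitted in FASTQ
  ctg2 <- make_contigs(other, ids = "ctg00001")
  al2 <- mapReads(rs, ctg2)
  asg2 <- new("ClusterAssignment", K = 1L,
              clusters = setNames(1L, "ctg00001"),
              responsibilities = matrix(1, 1L, 1L), seed = 1L)
  call2 <- callTargetClusters(hits, asg2)
  fq <- withr::local_tempfile(fileext = ".fastq")
  call2 <- rescueReads(al2, call2, rs, fastq_path = fq)
  expect_equal(rescuedReads(call2), "p2/1")
  written <- readFastq(fq)
  expect_setequal(names(readSequences(written)), c("p2/1", "p2/2"))
})
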