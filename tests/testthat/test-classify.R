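test_that("fragment coverage counts spanning reads per position", {
  expect_equal(fragment_coverage_profile("c1", 5L, empty_recs()), integer(5))
  recs <- rbind(make_rec("a", "c1", 0, cigar = "10M"),
                make_rec("b", "c1", 5, cigar = "10M"))
  fc <- fragment_coverage_profile("c1", 15L, recs)
  expect_equal(fc, c(rep(1L, 5), rep(2L, 5), rep(1L, 5)))

  # brute-force oracle on a random fixture
  set.seed(5)
  starts <- sample(0:90, 30, replace = TRUE)
  recs2 <- do.call(rbind, lapply(seq_along(starts), function(i) {
    make_rec(paste0("r", i), "c1", starts[i], cigar = "10M")
  }))
  fc2 <- fragment_coverage_profile("c1", 100L, recs2)
  brute <- vapply(1:100, function(j) {
    sum(starts < j & starts + 10 >= j)
  }, integer(1))
  expect_equal(fc2, brute)
})

test_that("coverage cutoff is alpha times the mean", {
  expect_equal(coverage_cutoff(c(4, 4, 4, 4), 0.5), 2)
  expect_equal(coverage_cutoff(c(3, 5, 1), 1), 3)
  expect_equal(coverage_cutoff(c(0, 10), 0.4), 2)
})

test_that("candidate regions are maximal low-coverage runs with leftmost-min breakpoints", {
  r <- detect_candidate_regions(c(5, 5, 1, 1, 5), 2)
  expect_equal(nrow(r), 1L)
  expect_equal(r$m, 3L); expect_equal(r$n, 4L); expect_equal(r$b_p, 3L)

  expect_equal(nrow(detect_candidate_regions(c(5, 6, 7), 2)), 0L)

  r2 <- detect_candidate_regions(c(1, 5, 1), 2)
  expect_equal(r2$b_p, c(1L, 3L))
  expect_equal(r2$m, c(1L, 3L))

  # run-length oracle on a random profile
  set.seed(9)
  fc <- rpois(200, 8)
  star <- coverage_cutoff(fc, 0.5)
  got <- detect_candidate_regions(fc, star)
  low <- which(fc <= star)
  expect_equal(sort(unlist(mapply(seq, got$m, got$n))), low)
  for (i in seq_len(nrow(got))) {
    seg <- fc[got$m[i]:got$n[i]]
    expect_equal(got$b_p[i], got$m[i] + which.min(seg) - 1L)
  }

  # edge trim masks contig ends
  r3 <- detect_candidate_regions(c(0, 0, 5, 5, 5, 0, 0), 2, edge_trim = 2L)
  expect_equal(nrow(r3), 0L)
  # monotonicity: raising alpha never removes a flagged position (runs can
  # merge, so the region count itself is not monotone)
  n_pos <- vapply(c(0.25, 0.5, 0.75, 1), function(a) {
    r <- detect_candidate_regions(fc, coverage_cutoff(fc, a))
    sum(r$n - r$m + 1L)
  }, numeric(1))
  expect_true(all(diff(n_pos) >= 0))
})

test_that("mate support rates follow fc/(fc+M) with the 0/0 convention", {
  # 8 cross-contig mates in the left flank of b_p = 100
  recs <- do.call(rbind, lapply(1:8, function(i) {
    make_rec(paste0("x", i), "c1", 100L - 10L - i, cigar = "10M",
             mate_contig_id = "c2")
  }))
  ms <- mate_support_rates(100L, 2L, "c1", recs, flank = 50L)
  expect_equal(ms$M_s, 8L)
  expect_equal(ms$P_cs, 2 / (2 + 8))
  expect_equal(ms$P_cp, 1)  # no right-flank support, fc > 0

  ms2 <- mate_support_rates(100L, 0L, "c1", empty_recs(), flank = 50L)
  expect_equal(ms2$P_cs, 1)  # 0/0 convention
  expect_equal(ms2$P_cp, 1)
})

test_that("GC content and region labels use the percent band", {
  expect_equal(genome_gc_content(contig_set(c(a = "GC", b = "AT"), "s")), 50)
  expect_equal(genome_gc_content(contig_set(c(a = "GGGG"), "s")), 100)
  # N counts in the denominator only
  expect_equal(genome_gc_content(contig_set(c(a = "GCNN"), "s")), 50)
  # brute-force oracle
  set.seed(3)
  s <- paste(sample(c("A", "C", "G", "T"), 500, replace = TRUE), collapse = "")
  expect_equal(genome_gc_content(contig_set(c(a = s), "s")),
               100 * lengths(regmatches(s, gregexpr("[GC]", s))) / 500)

  seqc <- strrep("G", 100)
  expect_equal(region_gc_label(1, 100, seqc, p_g = 50)$label, "rich")
  half <- paste0(strrep("GC", 25), strrep("AT", 25))
  expect_equal(region_gc_label(1, 100, half, p_g = 50)$label, "neutral")
  # 48.9% GC vs P_g 50: below the -1 point band edge
  mostly <- paste0(strrep("G", 489), strrep("A", 511))
  expect_equal(region_gc_label(1, 1000, mostly, p_g = 50)$label, "poor")
})

test_that("classify_and_break splits at certainly-false joints and labels U/T", {
  # clean contig, uniform coverage: no regions, label T. The sequence is
  # periodic so every window is exactly 50% GC (the rescue band is +-1 point).
  L <- 2000L
  seqc <- strrep("ACGT", L / 4)
  set <- contig_set(c(c1 = seqc), "s")
  recs <- do.call(rbind, lapply(seq(0, L - 50, by = 5), function(s) {
    make_rec(paste0("r", s), "c1", s, cigar = "50M")
  }))
  res <- classify_and_break(set, recs, alpha = 0.5, edge_trim = 50L)
  expect_equal(res$classification$c1$label, "T")
  expect_equal(length(res$set$contigs), 1L)

  # coverage hole with cross-contig mates on both flanks: certainly false,
  # contig split at b_p, both fragments T; total length conserved
  gap_recs <- recs[!(recs$start > 900 & recs$start < 1050), , drop = FALSE]
  cross <- do.call(rbind, lapply(1:20, function(i) {
    rbind(make_rec(paste0("xl", i), "c1", 850L + i, cigar = "50M",
                   mate_contig_id = "other"),
          make_rec(paste0("xr", i), "c1", 1050L + i, cigar = "50M",
                   mate_contig_id = "other"))
  }))
  res2 <- classify_and_break(set, rbind(gap_recs, cross), alpha = 0.5,
                             beta = 0.8, flank = 150L, min_fragment = 100L,
                             edge_trim = 50L)
  expect_equal(length(res2$set$contigs), 2L)
  expect_equal(sum(nchar(res2$set$contigs)), L)   # splitting conserves length
  expect_equal(unname(vapply(res2$classification, `[[`, "", "label")),
               c("T", "T"))
  expect_true(all(res2$regions$verdict == "certainly_false"))
  expect_true(res2$regions$b_p[1] > 900 && res2$regions$b_p[1] < 1060)

  # same hole but GC-rich neighbourhood: rescued as uncertain, no split
  gcrich <- paste0(substr(seqc, 1, 900), strrep("GC", 100),
                   substr(seqc, 1101, L))
  set3 <- contig_set(c(c1 = gcrich), "s3")
  res3 <- classify_and_break(set3, rbind(gap_recs, cross), alpha = 0.5,
                             beta = 0.8, flank = 150L, min_fragment = 100L,
                             edge_trim = 50L)
  expect_equal(length(res3$set$contigs), 1L)
  expect_equal(res3$classification$c1$label, "U")
  expect_true(length(res3$classification$c1$error_positions) >= 1L)
  expect_true(all(res3$regions$verdict == "uncertain"))
})
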