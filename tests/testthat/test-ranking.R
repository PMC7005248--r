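test_that("position profile votes by MAPQ relative to the mean and walks CIGARs", {
  # one read, mapq 50 >= mean 30: all M positions +1
  r <- make_rec("r1", "c1", 0, cigar = "10M", mapq = 50L)
  q <- position_quality_profile("c1", 20L, r, mean_mapq = 30)
  expect_equal(q[1:10], rep(1L, 10))
  expect_equal(q[11:20], rep(0L, 10))

  # low mapq: M runs vote -1
  r2 <- make_rec("r2", "c1", 0, cigar = "5M", mapq = 10L)
  expect_equal(position_quality_profile("c1", 5L, r2, 30)[1:5], rep(-1L, 5))

  # 4M2D4M, high mapq: deleted reference positions -1, M positions +1
  r3 <- make_rec("r3", "c1", 2, cigar = "4M2D4M", mapq = 60L)
  q3 <- position_quality_profile("c1", 12L, r3, 30)
  expect_equal(q3, c(0L, 0L, 1L, 1L, 1L, 1L, -1L, -1L, 1L, 1L, 1L, 1L))

  # insertion charges the preceding reference position
  r4 <- make_rec("r4", "c1", 0, cigar = "3M2I4M", mapq = 60L)
  q4 <- position_quality_profile("c1", 7L, r4, 30)
  expect_equal(q4, c(1L, 1L, 0L, 1L, 1L, 1L, 1L))  # +1 and -1 cancel at pos 3

  # multi-read aggregation is summed then sign-clamped
  r5 <- rbind(make_rec("a", "c1", 0, cigar = "4M", mapq = 60L),
              make_rec("b", "c1", 0, cigar = "4M", mapq = 60L),
              make_rec("c", "c1", 0, cigar = "4M", mapq = 0L))
  expect_equal(position_quality_profile("c1", 4L, r5, 30), rep(1L, 4))

  # = and X bypass the MAPQ heuristic
  r6 <- make_rec("r6", "c1", 0, cigar = "3=2X", mapq = 0L)
  expect_equal(position_quality_profile("c1", 5L, r6, 30),
               c(1L, 1L, 1L, -1L, -1L))

  expect_error(position_quality_profile("c1", 5L,
                                        make_rec("r", "c1", 3, cigar = "5M"), 30),
               "outside")
})

test_that("coverage flags mark reads on deviant pileups", {
  # uniform tiling: all rc_i equal, sigma 0, all flags -1
  recs <- do.call(rbind, lapply(0:9, function(i) {
    make_rec(paste0("r", i), "c1", i * 10L, cigar = "10M")
  }))
  cf <- coverage_flags("c1", 100L, recs)
  expect_equal(cf$sigma_rc, 0)
  expect_equal(cf$flags, rep(-1L, 10))

  # a deep stack among 1-deep neighbours: stacked reads flagged +1
  tile <- do.call(rbind, lapply(0:99, function(i) {
    make_rec(paste0("t", i), "c1", i * 10L, cigar = "10M")
  }))
  stack <- do.call(rbind, lapply(1:8, function(i) {
    make_rec(paste0("s", i), "c1", 100L, cigar = "10M")
  }))
  cf2 <- coverage_flags("c1", 1000L, rbind(tile, stack))
  flags <- setNames(cf2$flags, rbind(tile, stack)$read_id)
  expect_true(all(flags[paste0("s", 1:8)] == 1L))
  expect_equal(unname(flags["t10"]), 1L)  # the tile under the stack
  expect_true(all(flags[paste0("t", c(0:9, 11:99))] == -1L))
  # brute-force depth oracle for rc_i of one stacked read
  depth <- integer(1000)
  for (s in c(0:99 * 10L, rep(100L, 8))) {
    depth[(s + 1):(s + 10)] <- depth[(s + 1):(s + 10)] + 1L
  }
  expect_equal(cf2$rc_i[101], mean(depth[101:110]))

  # single read: rc_i = rc_bar, flag -1
  cf3 <- coverage_flags("c1", 50L, make_rec("solo", "c1", 0))
  expect_equal(cf3$flags, -1L)
})

test_that("assembly score follows (sum_q - sum_rc)/N and is order/scale invariant", {
  set <- contig_set(c(c1 = strrep("A", 10)), "s1")
  # one high-mapq read covering all 10 positions: sum_q 10; one read: RC -1
  rec <- make_rec("r1", "c1", 0, cigar = "10M", mapq = 60L)
  sc <- assembly_score(set, rec)
  expect_equal(sc$score, (10 - (-1)) / 1)

  # duplicating contig + alignments leaves the score unchanged
  set2 <- contig_set(c(c1 = strrep("A", 10), c2 = strrep("A", 10)), "s2")
  rec2 <- rbind(rec, make_rec("r2", "c2", 0, cigar = "10M", mapq = 60L))
  expect_equal(assembly_score(set2, rec2)$score, sc$score)

  # contig order within the set does not matter
  set3 <- contig_set(set2$contigs[c(2, 1)], "s3")
  expect_equal(assembly_score(set3, rec2)$score, sc$score)

  # independent brute-force recomputation on a random fixture
  set.seed(7)
  starts <- sample(0:40, 12, replace = TRUE)
  mapqs <- sample(0:60, 12, replace = TRUE)
  recs <- do.call(rbind, lapply(1:12, function(i) {
    make_rec(paste0("r", i), "c1", starts[i], cigar = "10M", mapq = mapqs[i])
  }))
  setr <- contig_set(c(c1 = strrep("A", 50)), "sr")
  got <- assembly_score(setr, recs)
  # oracle: direct per-position vote + per-read depth flags
  mm <- mean(mapqs)
  vote <- numeric(50)
  for (i in 1:12) {
    vote[(starts[i] + 1):(starts[i] + 10)] <-
      vote[(starts[i] + 1):(starts[i] + 10)] + ifelse(mapqs[i] >= mm, 1, -1)
  }
  depth <- numeric(50)
  for (i in 1:12) {
    depth[(starts[i] + 1):(starts[i] + 10)] <-
      depth[(starts[i] + 1):(starts[i] + 10)] + 1
  }
  rc_i <- vapply(1:12, function(i) mean(depth[(starts[i] + 1):(starts[i] + 10)]),
                 numeric(1))
  fl <- ifelse(abs(rc_i - mean(rc_i)) > 2 * sd(rc_i), 1, -1)
  expect_equal(got$sum_q, sum(sign(vote)))
  expect_equal(got$sum_rc, sum(fl))
  expect_equal(got$score, (sum(sign(vote)) - sum(fl)) / 1)
})

test_that("rank_assemblies is descending and stable, and recovers planted quality", {
  s <- list(list(set_id = "A", score = 5), list(set_id = "B", score = 9))
  expect_equal(rank_assemblies(s), c("B", "A"))
  s2 <- list(list(set_id = "A", score = 5), list(set_id = "B", score = 5))
  expect_equal(rank_assemblies(s2), c("A", "B"))

  # planted-quality recovery: equal contig counts, one assembly chimeric at a
  # position where the other is contiguous
  G <- 60000L
  gen <- simulate_genome(G, seed = 31)
  plans <- list(
    good = assembly_plan_from_breaks(G, c(15000, 35000)),
    bad = list(data.frame(start = c(0, 35000), end = c(15000, 50000)),
               data.frame(start = 15000, end = 35000),
               data.frame(start = 50000, end = 60000))
  )
  sa <- simulate_assemblies(gen, plans)
  sim <- simulate_reads(gen, 6000, read_len = 100, insert_mu = 300,
                        insert_sigma = 30, seed = 32)
  scores <- lapply(c("good", "bad"), function(a) {
    rec <- simulate_alignments(sim, sa$truth[sa$truth$set_id == a, ])
    assembly_score(sa$sets[[a]], preprocess_alignments(rec)$records)
  })
  expect_equal(rank_assemblies(scores)[1], "good")
})
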