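test_that("align_pair handles the elementary cases", {
  a <- align_pair("ACGT", "ACGT")
  expect_equal(a$identity, 1.0)
  expect_equal(a$aln_len, 4L)
  expect_equal(a$score, 4L)

  b <- align_pair("ACGT", "AGGT")
  expect_equal(b$identity, 0.75)
  expect_equal(b$aln_len, 4L)
  # one substitution, no gaps, in the edit script
  expect_false(grepl("-", b$a_aln, fixed = TRUE))
  expect_false(grepl("-", b$b_aln, fixed = TRUE))
  expect_equal(sum(strsplit(b$a_aln, "")[[1]] != strsplit(b$b_aln, "")[[1]]),
               1L)

  expect_error(align_pair(strrep("A", 30), strrep("A", 10), max_len = 20),
               "find_local_matches")
})

test_that("align_pair is deterministic and agrees with an independent DP", {
  set.seed(10)
  for (rep in 1:5) {
    x <- rnd_dna(500)
    y <- mutate_n(x, 50)   # ~90% identity
    r1 <- align_pair(x, y)
    r2 <- align_pair(x, y)
    expect_identical(r1, r2)   # deterministic tie-breaking, double run
    expect_gte(r1$identity, 0.88)
    expect_lte(r1$identity, 1.0)
    # independent oracle: Biostrings pairwise DP under the same scores
    sm <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1)
    ora <- Biostrings::pairwiseAlignment(x, y, substitutionMatrix = sm,
                                         gapOpening = 0, gapExtension = 2,
                                         type = "global", scoreOnly = TRUE)
    expect_equal(r1$score, as.integer(ora))
  }
})

test_that("a planted segment is recovered with tight boundaries", {
  set.seed(11)
  bg <- rnd_dna(50000)
  planted <- rnd_dna(2000)
  mut <- mutate_n(planted, 30)   # 98.5% identity
  q <- paste0(substr(bg, 1, 20000), mut, substr(bg, 20001, 50000))
  m <- find_local_matches(circular_seq("q", q, circular = FALSE),
                          circular_seq("t", planted, circular = FALSE),
                          min_len = 1000, min_identity = 0.9)
  expect_equal(nrow(m), 1L)
  expect_lte(abs(m$q_start - 20001L), 20L)
  expect_lte(abs(m$q_end - 22000L), 20L)
  # oracle: exhaustive DP on the planted pair
  ora <- align_pair(mut, planted)
  expect_lte(abs(m$identity - ora$identity), 0.01)
})

test_that("reverse-complement inserts are reported on the minus strand", {
  set.seed(12)
  bg <- rnd_dna(20000)
  ins <- rnd_dna(1500)
  q <- paste0(substr(bg, 1, 9000), revcomp(ins), substr(bg, 9001, 20000))
  m <- find_local_matches(circular_seq("q", q, circular = FALSE),
                          circular_seq("t", ins, circular = FALSE),
                          min_len = 1000, min_identity = 0.95)
  expect_equal(nrow(m), 1L)
  expect_equal(m$strand, "-")
  expect_equal(m$identity, 1.0)
})

test_that("self-comparison suppresses the trivial diagonal; near-identical genomes align full length", {
  set.seed(13)
  s <- rnd_dna(10000)
  g <- circular_seq("g", s, circular = FALSE)
  expect_equal(nrow(find_local_matches(g, g, min_len = 100)), 0L)
  # one substitution: not a self-comparison, full-length match expected
  h <- circular_seq("h", mutate_n(s, 1), circular = FALSE)
  m <- find_local_matches(g, h, min_len = 1000, min_identity = 0.95)
  expect_equal(nrow(m), 1L)
  expect_equal(m$aln_len, 10000L)
  expect_equal(m$identity, 9999 / 10000)
})

test_that("seeded identities agree with the exhaustive DP within a point", {
  set.seed(14)
  for (rep in 1:4) {
    x <- rnd_dna(1500)
    y <- mutate_n(x, round(1500 * 0.07))
    m <- find_local_matches(circular_seq("a", x, circular = FALSE),
                            circular_seq("b", y, circular = FALSE),
                            min_len = 500, min_identity = 0.8)
    expect_gte(nrow(m), 1L)
    for (i in seq_len(nrow(m))) {
      ora <- align_pair(substr(x, m$q_start[i], m$q_end[i]),
                        substr(y, m$t_start[i], m$t_end[i]))
      expect_lte(abs(m$identity[i] - ora$identity), 0.01)
    }
  }
})

test_that("raising thresholds never adds matches", {
  set.seed(15)
  bg <- rnd_dna(30000)
  q <- paste0(bg, mutate_n(substr(bg, 1000, 4000), 150))
  qg <- circular_seq("q", q, circular = FALSE)
  tg <- circular_seq("t", bg, circular = FALSE)
  base <- find_local_matches(qg, tg, min_len = 100, min_identity = 0.7)
  for (mi in c(0.8, 0.9, 0.95)) {
    m <- find_local_matches(qg, tg, min_len = 100, min_identity = mi)
    expect_lte(nrow(m), nrow(base))
  }
  for (ml in c(500, 2000, 10000)) {
    m <- find_local_matches(qg, tg, min_len = ml, min_identity = 0.7)
    expect_lte(nrow(m), nrow(base))
  }
})

test_that("match sets are symmetric under role exchange", {
  set.seed(16)
  a <- rnd_dna(20000)
  b <- paste0(substr(a, 5001, 9000), rnd_dna(6000),
              revcomp(substr(a, 12001, 15000)))
  ga <- circular_seq("a", a, circular = FALSE)
  gb <- circular_seq("b", b, circular = FALSE)
  mab <- find_local_matches(ga, gb, min_len = 1000, min_identity = 0.95)
  mba <- find_local_matches(gb, ga, min_len = 1000, min_identity = 0.95)
  expect_equal(nrow(mab), nrow(mba))
  k1 <- with(as.data.frame(mab),
             sort(paste(q_start, q_end, t_start, t_end, strand)))
  k2 <- with(as.data.frame(mba),
             sort(paste(t_start, t_end, q_start, q_end, strand)))
  expect_equal(k1, k2)
})

test_that("matches cross the origin of a circular query", {
  set.seed(17)
  core <- rnd_dna(3000)
  bg <- rnd_dna(17000)
  # segment wraps: last 1500 bases + first 1500 bases of the circle
  g <- circular_seq("g", paste0(substr(core, 1501, 3000), bg,
                                substr(core, 1, 1500)))
  m <- find_local_matches(g, circular_seq("t", core, circular = FALSE),
                          min_len = 2000, min_identity = 0.95)
  expect_equal(nrow(m), 1L)
  expect_gt(m$q_start, m$q_end)  # wrapping interval
  expect_equal(m$aln_len, 3000L)
})

test_that("empty sequences are rejected", {
  expect_error(circular_seq("e", ""))
})
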