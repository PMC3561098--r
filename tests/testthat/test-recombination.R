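direct_pair <- function(s1, e1, s2, e2) {
  data.frame(kind = "direct", start1 = s1, end1 = e1,
             start2 = s2, end2 = e2, rep_len = e1 - s1 + 1L, identity = 1)
}

test_that("the published master circle resolves into the published subcircles", {
  set.seed(40)
  L <- 258473L
  rep_len <- 9731L
  base <- rnd_dna(L - rep_len)
  s1 <- 10000L; s2 <- s1 + 56610L
  g <- circular_seq("master",
                    paste0(substr(base, 1, s2 - 1L),
                           substr(base, s1, s1 + rep_len - 1L),
                           substr(base, s2, nchar(base))))
  expect_equal(g$length, L)
  circles <- predict_subgenomic_circles(
    g, direct_pair(s1, s1 + rep_len - 1L, s2, s2 + rep_len - 1L),
    emit_seq = FALSE)
  sizes <- sort(c(circles[[1]]$size, circles[[2]]$size))
  expect_equal(sizes, c(56610L, 201863L))
  expect_equal(sum(sizes), L)
})

test_that("symmetric copies split the circle in half", {
  set.seed(41)
  g <- circular_seq("g", rnd_dna(100))
  circles <- predict_subgenomic_circles(g, direct_pair(1L, 10L, 51L, 60L),
                                        emit_seq = FALSE)
  expect_equal(circles[[1]]$size, 50L)
  expect_equal(circles[[2]]$size, 50L)
})

test_that("predicted sizes match the position-list cut-and-rejoin oracle", {
  set.seed(42)
  for (rep in 1:100) {
    L <- sample(200:5000, 1)
    rep_len <- sample(10:40, 1)
    s1 <- sample.int(L %/% 3, 1)
    s2 <- s1 + rep_len + sample.int(L %/% 2, 1)
    if (s2 + rep_len - 1L > L) next
    g <- circular_seq("g", rnd_dna(L))
    circles <- predict_subgenomic_circles(
      g, direct_pair(s1, s1 + rep_len - 1L, s2, s2 + rep_len - 1L),
      emit_seq = FALSE)
    ora <- circle_cut_oracle(L, s1, s2)
    expect_equal(circles[[1]]$size, ora$size1)
    expect_equal(circles[[2]]$size, ora$size2)
    expect_equal(circles[[1]]$size + circles[[2]]$size, L)
    # base-content conservation across the split
    expect_equal(sort(c(ora$circle1, ora$circle2)), seq_len(L))
  }
})

test_that("recombining the two subcircles regenerates the master (rotation)", {
  set.seed(43)
  for (rep in 1:5) {
    L <- sample(1000:4000, 1)
    s1 <- 100L; s2 <- s1 + sample(300:(L %/% 2), 1)
    g <- circular_seq("g", rnd_dna(L))
    circles <- predict_subgenomic_circles(g, direct_pair(s1, s1 + 19L,
                                                         s2, s2 + 19L))
    rejoined <- paste0(circles[[1]]$seq$seq, circles[[2]]$seq$seq)
    expect_true(rotation_identical(rejoined, g$seq))
    expect_equal(canonical_rotation(rejoined), canonical_rotation(g$seq))
  }
})

test_that("inverted pairs are routed to the isomer model and vice versa", {
  g <- circular_seq("g", strrep("ACGT", 100))
  ip <- data.frame(kind = "inverted", start1 = 10, end1 = 19,
                   start2 = 210, end2 = 219, rep_len = 10, identity = 1)
  expect_error(predict_subgenomic_circles(g, ip), "direct repeat")
  dp <- direct_pair(10L, 19L, 210L, 219L)
  expect_error(predict_inverted_isomer(g, dp), "inverted repeat")
  lin <- circular_seq("lin", strrep("ACGT", 100), circular = FALSE)
  expect_error(predict_subgenomic_circles(lin, dp), "circular")
})

test_that("the inverted-repeat isomer is an involution and flips genes", {
  set.seed(44)
  bg <- rnd_dna(5000)
  orf <- paste0("ATG", strrep("CAT", 50), "TAA")
  g <- circular_seq("g", paste0(substr(bg, 1, 2000), orf,
                                substr(bg, 2001, 5000)))
  ip <- data.frame(kind = "inverted", start1 = 500, end1 = 599,
                   start2 = 4000, end2 = 4099, rep_len = 100, identity = 1)
  iso <- predict_inverted_isomer(g, ip)
  expect_equal(iso$length, g$length)
  expect_false(identical(iso$seq, g$seq))
  twice <- predict_inverted_isomer(iso, ip)
  expect_equal(twice$seq, g$seq)
  # the planted ORF sat inside the flipped arc: it is now on the minus strand
  expect_false(grepl(orf, iso$seq, fixed = TRUE))
  expect_true(grepl(revcomp(orf), iso$seq, fixed = TRUE))
  # zero-length inter-copy arc leaves the genome unchanged
  ip0 <- data.frame(kind = "inverted", start1 = 500, end1 = 599,
                    start2 = 600, end2 = 699, rep_len = 100, identity = 1)
  expect_equal(predict_inverted_isomer(g, ip0)$seq, g$seq)
})

test_that("junctions of a mediated block swap are explained by the planted repeat", {
  sim <- small_sim()
  syn <- detect_syntenic_regions(sim$cybrid, sim$recipient)
  reps <- find_repeats(sim$cybrid)
  je <- explain_junctions_by_repeats(syn, reps)
  expect_gt(nrow(je), 0L)
  pl <- je[je$plausible, ]
  expect_gt(nrow(pl), 0L)
  # the plausible mediators sit essentially on the breakpoints
  expect_true(all(pmax(pl$offset1, pl$offset2) <= 500L))
  # and they correspond to planted mediating repeat copies
  copies <- sim$truth$short_repeat_copies
  for (k in unique(pl$repeat_id)) {
    near <- any(abs(reps$start1[k] - copies$start) <= 30 |
                abs(reps$start2[k] - copies$start) <= 30)
    expect_true(near)
  }
})

test_that("an identical genome pair produces no rearrangement junctions", {
  set.seed(45)
  s <- rnd_dna(20000)
  syn <- detect_syntenic_regions(circular_seq("A", s), circular_seq("B", s))
  reps <- data.frame(kind = character(0), start1 = integer(0),
                     end1 = integer(0), start2 = integer(0),
                     end2 = integer(0), rep_len = integer(0),
                     identity = numeric(0))
  expect_equal(nrow(explain_junctions_by_repeats(syn, reps)), 0L)
})

test_that("a swap without a mediating repeat is reported but not plausible", {
  set.seed(46)
  s <- rnd_dna(40000)
  # swap two internal blocks with no repeat at the breakpoints
  b <- paste0(substr(s, 1, 10000), substr(s, 25001, 32000),
              substr(s, 10001, 25000), substr(s, 32001, 40000))
  syn <- detect_syntenic_regions(circular_seq("A", b), circular_seq("B", s))
  reps <- find_repeats(circular_seq("A", b))
  je <- explain_junctions_by_repeats(syn, reps)
  expect_gt(nrow(je), 0L)
  expect_false(any(je$plausible))
})
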