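test_that("substitution classification partitions all 12 ordered base pairs", {
  bases <- c("A", "C", "G", "T")
  pairs <- expand.grid(ref = bases, alt = bases, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$ref != pairs$alt, ]
  cls <- classify_substitution(pairs$ref, pairs$alt)
  expect_equal(sum(cls == "transition"), 4L)
  expect_equal(sum(cls == "transversion"), 8L)
  expect_equal(classify_substitution("C", "T"), "transition")
  expect_equal(classify_substitution("T", "G"), "transversion")
  expect_error(classify_substitution("A", "A"), "differ")
  expect_error(classify_substitution("N", "A"), "one of")
})

test_that("the classifier reproduces every published SNP-type label", {
  tab <- published_snps()
  expect_equal(nrow(tab), 39L)
  cls <- classify_substitution(tab$ref, tab$alt)
  expect_equal(cls, tab$snp_type)
  # 13 synonymous among the printed rows
  expect_equal(sum(tab$effect == "S"), 13L)
  # codon-index arithmetic for every row with a printed codon index
  has_ci <- !is.na(tab$codon_index)
  expect_true(any(has_ci))
  expect_equal(ceiling(tab$cds_pos[has_ci] / 3), tab$codon_index[has_ci])
})

test_that("gene SNP calling reproduces published codon-level examples", {
  set.seed(60)
  # nad1-style: position 571 C->T is codon 191 CTT->TTT, Leu->Phe
  # codon 1 = ATG, codons 2..199 random sense codons, codon 200 = TAA
  cods <- sample(setdiff(names(Biostrings::GENETIC_CODE),
                         c("TAA", "TAG", "TGA")), 198L, replace = TRUE)
  cods[190L] <- "CTT"       # codon 191 of the CDS
  ref <- paste0("ATG", paste(cods, collapse = ""), "TAA")
  alt <- ref
  substr(alt, 571L, 571L) <- "T"   # CTT -> TTT
  sn <- call_gene_snps(ref, alt, "nad1")
  expect_equal(nrow(sn), 1L)
  expect_equal(sn$cds_pos, 571L)
  expect_equal(sn$codon_index, 191L)
  expect_equal(sn$ref_aa, "L")
  expect_equal(sn$alt_aa, "F")
  expect_equal(sn$effect, "non-synonymous")
  expect_equal(sn$snp_type, "transition")

  # atp9-style: position 64 A->G is codon 22 ATT->GTT, Ile->Val
  cods3 <- cods[seq_len(98L)]
  cods3[98L] <- "GGC"       # keep the CDS free of accidental stops
  cods3[21L] <- "ATT"       # codon 22
  ref2 <- paste0("ATG", paste(cods3, collapse = ""), "TAA")
  alt2 <- ref2
  substr(alt2, 64L, 64L) <- "G"
  sn2 <- call_gene_snps(ref2, alt2, "atp9")
  expect_equal(nrow(sn2), 1L)
  expect_equal(sn2$codon_index, 22L)
  expect_equal(sn2$ref_aa, "I")
  expect_equal(sn2$alt_aa, "V")
  expect_equal(sn2$snp_type, "transition")

  # identical CDSs give an empty call set
  expect_equal(nrow(call_gene_snps(ref, ref, "x")), 0L)
  # unequal lengths are boundary-shift territory
  expect_error(call_gene_snps(ref, paste0(ref, "AAA"), "x"),
               "detect_boundary_shift")
})

test_that("multi-hit codons are translated jointly and internal stops warn", {
  ref <- paste0("ATG", "CTT", "TAA")       # M L *
  alt <- paste0("ATG", "GAC", "TAA")       # codon 2 hit at all 3 sites
  sn <- call_gene_snps(ref, alt, "joint")
  expect_equal(nrow(sn), 3L)
  expect_true(all(sn$codon_index == 2L))
  expect_true(all(sn$ref_aa == "L"))
  expect_true(all(sn$alt_aa == "D"))
  expect_true(all(sn$effect == "non-synonymous"))
  # internal stop: warning, classification continues
  ref3 <- paste0("ATG", "TAA", "CTT", "TAA")
  alt3 <- paste0("ATG", "TAA", "CTC", "TAA")
  expect_warning(sn3 <- call_gene_snps(ref3, alt3, "stopgene"), "stop")
  expect_equal(nrow(sn3), 1L)
  expect_equal(sn3$effect, "synonymous")
})

test_that("boundary-shift detection reports the published 27 and 498 bp shifts", {
  # tatC-style: stop disrupted, next in-frame stop 9 codons downstream
  cs <- shift_construct(61, shift3 = 27L)
  bs <- detect_boundary_shift(cs$model, cs$ref, cs$alt)
  expect_equal(nrow(bs), 1L)
  expect_equal(bs$end, "3prime")
  expect_equal(bs$shift_len, 27L)

  # atp6-style: 498 bp in-frame ATG-led prefix (start codon included)
  cs2 <- shift_construct(62, shift5 = 498L)
  bs2 <- detect_boundary_shift(cs2$model, cs2$ref, cs2$alt)
  expect_equal(nrow(bs2), 1L)
  expect_equal(bs2$end, "5prime")
  expect_equal(bs2$shift_len, 498L)

  # unmodified ortholog: no shifts
  cs3 <- shift_construct(63)
  expect_equal(nrow(detect_boundary_shift(cs3$model, cs3$ref, cs3$alt)), 0L)
})

test_that("planted shift lengths are recovered exactly on random constructs", {
  set.seed(64)
  n_ok <- 0L; n <- 0L
  for (rep in 1:50) {
    which_end <- sample(c("5prime", "3prime"), 1)
    strand <- sample(c("+", "-"), 1)
    len <- 3L * sample(3:60, 1)
    cs <- shift_construct(6400 + rep,
                          shift5 = if (which_end == "5prime") len else 0L,
                          shift3 = if (which_end == "3prime") len else 0L,
                          strand = strand)
    bs <- detect_boundary_shift(cs$model, cs$ref, cs$alt)
    n <- n + 1L
    if (nrow(bs) == 1L && bs$end == which_end && bs$shift_len == len) {
      n_ok <- n_ok + 1L
    }
  }
  expect_equal(n_ok, n)
})

test_that("ORF finding matches construction and handles both strands and wrap", {
  # planted minimal ORF
  set.seed(65)
  orf <- paste0("ATG", strrep("AAA", 33), "TAA")  # 105 bp
  g <- circular_seq("g", paste0("TAATAATAA", orf, rnd_dna(500)))
  found <- find_orfs(g, min_orf_len = 100L)
  hit <- found[found$seq == orf, ]
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$length, 105L)
  expect_equal(hit$strand, "+")

  # reverse-strand ORF: protein read from the reverse complement
  g2 <- circular_seq("g2", paste0(rnd_dna(300), revcomp(orf),
                                  revcomp("TAATAATAA"), rnd_dna(300)))
  found2 <- find_orfs(g2, min_orf_len = 100L)
  hit2 <- found2[found2$seq == orf, ]
  expect_equal(nrow(hit2), 1L)
  expect_equal(hit2$strand, "-")
  expect_equal(hit2$protein, substr(translate_cds(orf), 1, 34))

  # ORF spanning the circular origin
  half1 <- substr(orf, 1, 50); half2 <- substr(orf, 51, nchar(orf))
  g3 <- circular_seq("g3", paste0(half2, rnd_dna(400), "TAATAATAA", half1))
  found3 <- find_orfs(g3, min_orf_len = 100L)
  hit3 <- found3[found3$seq == orf, ]
  expect_equal(nrow(hit3), 1L)
  expect_true(hit3$wraps)
  expect_gt(hit3$start, hit3$end)
})

test_that("the scanner equals a brute-force six-frame oracle", {
  set.seed(66)
  for (rep in 1:3) {
    g <- circular_seq(paste0("g", rep), rnd_dna(2000))
    for (ml in c(60L, 150L, 300L)) {
      got <- find_orfs(g, min_orf_len = ml)
      ora <- brute_orfs(g, ml)
      expect_equal(nrow(got), nrow(ora))
      if (nrow(got)) {
        expect_equal(sort(got$length), sort(ora$length))
      }
    }
  }
  # a linear molecule must not report wrapping ORFs
  lin <- circular_seq("lin", rnd_dna(2000), circular = FALSE)
  got <- find_orfs(lin, min_orf_len = 60L)
  expect_false(any(got$wraps))
})

test_that("hydropathy windows find membrane-spanning segments", {
  # 30 leucines in a polar context
  p1 <- paste0(strrep("D", 20), strrep("L", 30), strrep("E", 20))
  tm1 <- predict_tm_segments(p1)
  expect_equal(nrow(tm1), 1L)
  expect_gte(tm1$end[1], 21L)
  expect_lte(tm1$start[1], 50L)
  # an all-polar protein has none
  expect_equal(nrow(predict_tm_segments(strrep("D", 60))), 0L)
  # two hydrophobic blocks separated by 40 polar residues
  p2 <- paste0(strrep("D", 10), strrep("L", 25), strrep("N", 40),
               strrep("L", 25), strrep("D", 10))
  expect_equal(nrow(predict_tm_segments(p2)), 2L)
  # short proteins and bad letters
  expect_equal(nrow(predict_tm_segments("MKL")), 0L)
  expect_error(predict_tm_segments(strrep("Z", 30)), "non-standard")
})

test_that("CMS screening ranks ORFs by the three published criteria", {
  set.seed(67)
  orfs <- data.frame(
    orf_id = c("orf138like", "shared1", "uniq_no_tm"),
    start = c(10000L, 20000L, 30000L),
    end = c(10413L, 20500L, 30600L),
    strand = "+",
    length = c(414L, 501L, 601L),
    protein = c(paste0("MK", strrep("L", 25), strrep("D", 100)),  # one TM
                paste0("M", strrep("D", 150)),
                paste0("M", strrep("E", 180))),
    sharedness = c("unique", "shared", "unique"),
    stringsAsFactors = FALSE)
  genes <- data.frame(gene_id = "atp6like", start = 10800L, end = 11600L)
  ranked <- screen_cms_candidates(orfs, genes, L = 60000L,
                                  proximity = 2000L)
  expect_equal(ranked$orf_id[1], "orf138like")
  expect_equal(ranked$n_criteria[1], 3L)
  expect_true(ranked$is_unique[1] && ranked$has_tm[1] && ranked$near_gene[1])
  # a shared ORF is never top-ranked
  expect_lt(ranked$n_criteria[ranked$orf_id == "shared1"], 3L)
  # unique ORF without TM scores 2 at most
  expect_lte(ranked$n_criteria[ranked$orf_id == "uniq_no_tm"], 2L)
})

test_that("simulator gene truth round-trips through SNP calling", {
  sim <- small_sim()
  tr <- sim$truth
  for (gi in seq_len(nrow(tr$genes_recipient))) {
    gr <- tr$genes_recipient[gi, ]
    gc_ <- tr$genes_cybrid[gi, ]
    if (gr$gene_id %in% tr$boundary_shifts$gene_id) next
    ref <- extract_interval(sim$recipient,
                            interval(gr$start, gr$end, gr$strand))
    alt <- extract_interval(sim$cybrid,
                            interval(gc_$start, gc_$end, gc_$strand))
    sn <- call_gene_snps(ref, alt, gr$gene_id)
    expect_sn <- tr$snps[tr$snps$gene_id == gr$gene_id, ]
    expect_equal(nrow(sn), nrow(expect_sn))
    if (nrow(sn)) {
      o1 <- sn[order(sn$cds_pos), ]
      o2 <- expect_sn[order(expect_sn$cds_pos), ]
      expect_equal(o1$cds_pos, o2$cds_pos)
      expect_equal(o1$snp_type, o2$snp_type)
      expect_equal(o1$effect == "synonymous", o2$effect == "synonymous")
    }
  }
  # the planted boundary shifts are recovered through the detector
  for (z in seq_len(nrow(tr$boundary_shifts))) {
    gid <- tr$boundary_shifts$gene_id[z]
    gi <- which(tr$genes_recipient$gene_id == gid)
    gm <- gene_model(gid, tr$genes_recipient[gi, c("start", "end", "strand")])
    bs <- detect_boundary_shift(gm, sim$recipient, sim$cybrid)
    expect_true(tr$boundary_shifts$shift_len[z] %in% bs$shift_len)
    expect_true(tr$boundary_shifts$end[z] %in% bs$end)
  }
})
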