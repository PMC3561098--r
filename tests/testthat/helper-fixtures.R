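# Shared fixtures: all built in code, cached across test files so the
# heavier simulations run once per suite.

.fixture_cache <- new.env(parent = emptyenv())

rnd_dna <- function(n, gc = 0.45) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

mutate_n <- function(s, n_subs) {
  v <- strsplit(s, "")[[1]]
  pos <- sample.int(length(v), n_subs)
  for (p in pos) v[p] <- sample(setdiff(c("A", "C", "G", "T"), v[p]), 1L)
  paste(v, collapse = "")
}

# small end-to-end simulation shared by several files
small_sim <- function() {
  if (is.null(.fixture_cache$small_sim)) {
    cfg <- sim_config(seed = 7, recipient_len = 60000L, n_blocks = 5L,
                      n_inversions = 2L, large_repeat_len = 3000L,
                      donor_segments = c(2220L, 469L, 5130L, 1052L),
                      cp_segments = c(2196L, 673L, 178L),
                      n_genes = 8L, n_coding_snps = 15L,
                      cp_len = 40000L, donor_len = 40000L)
    .fixture_cache$small_sim <- simulate_cybrid(cfg)
  }
  .fixture_cache$small_sim
}

# full-scale simulation at the published genome size, shared by the
# acceptance tests
full_sim <- function() {
  if (is.null(.fixture_cache$full_sim)) {
    .fixture_cache$full_sim <- simulate_cybrid(
      sim_config(seed = 101, final_len = 258473L))
  }
  .fixture_cache$full_sim
}

published_snps <- function() {
  read.delim(system.file("extdata", "published_snp_table.tsv",
                         package = "cybridmt"),
             stringsAsFactors = FALSE)
}

# independent brute-force six-frame ORF scanner (per-position walk)
brute_orfs <- function(g, min_orf_len) {
  L <- g$length
  hits <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") g$seq else cybridmt::revcomp(g$seq)
    ss <- if (g$circular) paste0(s, s) else s
    n <- nchar(ss)
    for (p in seq_len(min(L, n - 2L))) {
      if (substr(ss, p, p + 2L) != "ATG") next
      q <- p
      while (q + 2L <= n) {
        cod <- substr(ss, q, q + 2L)
        if (cod %in% c("TAA", "TAG", "TGA")) break
        q <- q + 3L
      }
      if (q + 2L > n) next
      cod <- substr(ss, q, q + 2L)
      if (!cod %in% c("TAA", "TAG", "TGA")) next
      len <- q + 2L - p + 1L
      if (len < min_orf_len || len > L) next
      hits[[length(hits) + 1L]] <- data.frame(stop_src = q, src = p,
                                              strand = strand, length = len)
    }
  }
  if (!length(hits)) {
    return(data.frame(stop_src = integer(0), src = integer(0),
                      strand = character(0), length = integer(0)))
  }
  h <- do.call(rbind, hits)
  # longest ORF per (stop, strand); collapse origin-duplicated stops
  h$stop_mod <- (h$stop_src - 1L) %% L + 1L
  h <- h[order(h$strand, h$stop_mod, -h$length), ]
  h <- h[!duplicated(h[, c("strand", "stop_mod")]), ]
  h
}

# position-list oracle for direct-repeat recombination: literally cut
# the circle's position list at the two copy starts and rejoin
circle_cut_oracle <- function(L, s1, s2) {
  pos <- seq_len(L)
  rot <- c(pos[s1:L], if (s1 > 1) pos[1:(s1 - 1)])  # circle opened at s1
  k <- which(rot == s2)
  list(size1 = k - 1L, size2 = L - (k - 1L),
       circle1 = rot[seq_len(k - 1L)], circle2 = rot[k:L])
}

# build a genome pair where one gene's boundaries are shifted
shift_construct <- function(seed, shift5 = 0L, shift3 = 0L, strand = "+") {
  set.seed(seed)
  ncod <- 120L
  cds <- paste0("ATG", paste(sample(setdiff(
    apply(expand.grid(c("A","C","G","T"), c("A","C","G","T"),
                      c("A","C","G","T")), 1, paste, collapse = ""),
    c("TAA", "TAG", "TGA")), ncod - 2L, replace = TRUE), collapse = ""),
    "TAA")
  up <- rnd_dna(3000); dn <- rnd_dna(3000)
  # reference genome: a stop immediately upstream keeps its own 5'
  # extension at zero
  ref_txt <- paste0(up, "TAA", cds, dn)
  gstart <- nchar(up) + 4L
  gend <- gstart + nchar(cds) - 1L
  alt_cds_region <- cds
  alt_up <- paste0(up, "TAA")
  alt_dn <- dn
  if (shift5 > 0L) {
    ext <- paste0("ATG", paste(sample(setdiff(
      apply(expand.grid(c("A","C","G","T"), c("A","C","G","T"),
                        c("A","C","G","T")), 1, paste, collapse = ""),
      c("TAA", "TAG", "TGA")), shift5 / 3L - 1L, replace = TRUE),
      collapse = ""))
    alt_up <- paste0(up, "TAA", ext)   # in-frame ATG-led prefix
  }
  if (shift3 > 0L) {
    k <- shift3 %/% 3L
    flank <- paste0(paste(sample(setdiff(
      apply(expand.grid(c("A","C","G","T"), c("A","C","G","T"),
                        c("A","C","G","T")), 1, paste, collapse = ""),
      c("TAA", "TAG", "TGA")), k - 1L, replace = TRUE), collapse = ""),
      "TAA")
    substr(alt_cds_region, nchar(alt_cds_region) - 2L,
           nchar(alt_cds_region) - 2L) <- "C"  # disrupt the stop
    alt_dn <- paste0(flank, substr(dn, shift3 + 1L, nchar(dn)))
  }
  alt_txt <- paste0(alt_up, alt_cds_region, alt_dn)
  if (strand == "-") {
    Lr <- nchar(ref_txt)
    gm <- gene_model("g", data.frame(start = Lr - gend + 1L,
                                     end = Lr - gstart + 1L,
                                     strand = "-"))
    ref_txt <- revcomp(ref_txt)
    alt_txt <- revcomp(alt_txt)
  } else {
    gm <- gene_model("g", data.frame(start = gstart, end = gend,
                                     strand = "+"))
  }
  list(ref = circular_seq("ref", ref_txt), alt = circular_seq("alt", alt_txt),
       model = gm)
}

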