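# Synthetic cybrid-mitogenome generator with full ground truth.  The
# emitted system mirrors the inferred history of a somatic-hybrid
# mitogenome: a recipient-like circular backbone with planted gene
# models; comparator genomes that are recipient-derived (neutral noise
# and block moves, no exogenous content); and a cybrid built by block
# rearrangement with planted mediating repeats, donor- and
# chloroplast-derived insertions, a duplicated large repeat, coding SNPs
# with a transition excess, and gene boundary shifts.  Every planted
# feature is recorded in final cybrid coordinates.

NONSTOP_CODONS <- setdiff(
  apply(expand.grid(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                    c("A", "C", "G", "T")), 1, paste, collapse = ""),
  c("TAA", "TAG", "TGA"))

random_dna <- function(n, gc = 0.45) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

mutate_seq <- function(s, n_subs) {
  if (n_subs <= 0L) return(s)
  v <- strsplit(s, "")[[1]]
  pos <- sample.int(length(v), min(n_subs, length(v)))
  for (p in pos) {
    v[p] <- sample(setdiff(c("A", "C", "G", "T"), v[p]), 1L)
  }
  paste(v, collapse = "")
}

comp_base <- function(b) chartr("ACGT", "TGCA", b)

#' Simulation configuration for the synthetic cybrid system
#'
#' Defaults emulate the study system: a recipient mitotype of 221,853 bp
#' at 45.2% GC, a 9,731 bp duplicated large repeat, mediating short
#' repeats of 310 and 232 bp, eleven donor-derived segments with the
#' published unique-region lengths, six chloroplast-derived segments
#' with the published MTPT lengths, 40 coding SNPs at a 29/40 transition
#' bias, and 5'/3' gene boundary shifts of 498 and 27 bp.
#'
#' @param seed integer seed; mandatory, all randomness flows from it.
#' @param recipient_len recipient backbone length in bp.
#' @param gc recipient/cybrid GC fraction.
#' @param n_blocks number of rearrangement blocks.
#' @param n_inversions number of inverted blocks.
#' @param large_repeat_len duplicated large-repeat length in bp.
#' @param short_repeats data.frame(len, identity): mediating repeats
#'   planted at rearrangement junctions (two copies each).
#' @param donor_segments lengths (bp) of donor-derived insertions.
#' @param cp_segments lengths (bp) of chloroplast-derived insertions.
#' @param cp_identity identity of planted cp segments to their plastid
#'   source.
#' @param cp_len,cp_gc chloroplast genome length and GC.
#' @param donor_len donor mitotype length.
#' @param n_genes,gene_len_range planted protein-gene count and CDS
#'   length range (bp, multiples of 3 are enforced).
#' @param n_coding_snps coding substitutions planted in the cybrid.
#' @param titv_bias fraction of SNPs drawn as transitions.
#' @param boundary_shifts list of list(end=,len=) gene-model shifts.
#' @param comparator_n,comparator_sub_rate,comparator_max_moves
#'   comparator count, substitution rate and maximum neutral block
#'   moves.
#' @param final_len if non-NULL, the recipient is sized so the cybrid
#'   comes out exactly this long.
#' @param min_insert_sep minimum spacing between insertion points (bp).
#' @return a list of class \code{SimConfig}.
#' @export
sim_config <- function(seed,
                       recipient_len = 221853L, gc = 0.4521,
                       n_blocks = 6L, n_inversions = 2L,
                       large_repeat_len = 9731L,
                       short_repeats = data.frame(len = c(310L, 232L),
                                                  identity = c(1, 1)),
                       donor_segments = c(2220L, 2220L, 469L, 469L, 5130L,
                                          1052L, 445L, 3572L, 2700L, 3828L,
                                          879L),
                       cp_segments = c(2196L, 1880L, 1362L, 1159L, 673L,
                                       178L),
                       cp_identity = 0.97, cp_len = 153000L, cp_gc = 0.37,
                       donor_len = 240000L,
                       n_genes = 20L, gene_len_range = c(300L, 1500L),
                       n_coding_snps = 40L, titv_bias = 29 / 40,
                       boundary_shifts = list(list(end = "5prime", len = 498L),
                                              list(end = "3prime", len = 27L)),
                       comparator_n = 6L, comparator_sub_rate = 0.005,
                       comparator_max_moves = 3L,
                       final_len = NULL, min_insert_sep = 600L) {
  if (missing(seed)) stop("a seed is mandatory for reproducibility")
  cfg <- as.list(environment())
  stopifnot(all(cfg$donor_segments > 0), all(cfg$cp_segments > 0),
            gc >= 0, gc <= 1, titv_bias >= 0, titv_bias <= 1,
            n_inversions <= n_blocks)
  class(cfg) <- "SimConfig"
  cfg
}

# place n non-overlapping intervals of given lengths with min gaps
place_intervals <- function(L, lens, min_gap, edge, max_try = 5000L) {
  starts <- integer(0); ends <- integer(0)
  for (len in lens) {
    ok <- FALSE
    for (try in seq_len(max_try)) {
      s <- sample.int(L - len - 2L * edge, 1L) + edge
      e <- s + len - 1L
      if (!length(starts) ||
          all(s > ends + min_gap | e < starts - min_gap)) {
        starts <- c(starts, s); ends <- c(ends, e); ok <- TRUE; break
      }
    }
    if (!ok) stop("capacity error: could not place an interval of ", len,
                  " bp; genome too small for the requested features")
  }
  data.frame(start = starts, end = ends)
}

in_zones <- function(p, zones) {
  any(p >= zones$start & p <= zones$end)
}

#' Simulate a cybrid mitogenome system with ground truth
#'
#' Deterministic for a given seed (the caller's RNG state is restored on
#' exit).  Construction order: recipient backbone with planted genes;
#' comparators as recipient plus neutral noise; cybrid as the recipient
#' carrying planted coding SNPs and boundary shifts, cut into blocks,
#' permuted and partly inverted, with mediating repeats at junctions and
#' donor/chloroplast segments plus a duplicated large repeat inserted.
#'
#' @param cfg a \code{\link{sim_config}}.
#' @return list of class \code{cybrid_sim} with elements
#'   \code{recipient}, \code{comparators}, \code{donor}, \code{cp},
#'   \code{cybrid} (all CircularSeq) and \code{truth} (feature catalogue
#'   in final cybrid coordinates).
#' @export
simulate_cybrid <- function(cfg) {
  stopifnot(inherits(cfg, "SimConfig"))
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                   envir = globalenv())
  })
  set.seed(cfg$seed)

  nshort <- nrow(cfg$short_repeats)
  insert_total <- sum(cfg$donor_segments) + sum(cfg$cp_segments) +
    cfg$large_repeat_len + 2L * sum(cfg$short_repeats$len)
  Lr <- if (!is.null(cfg$final_len)) {
    as.integer(cfg$final_len) - insert_total
  } else {
    as.integer(cfg$recipient_len)
  }
  if (Lr < 20000L) stop("capacity error: recipient backbone of ", Lr,
                        " bp cannot host the requested features")

  ## recipient backbone with planted genes ------------------------------
  rec <- random_dna(Lr, cfg$gc)
  glens <- 3L * round(runif(cfg$n_genes, cfg$gene_len_range[1] / 3,
                            cfg$gene_len_range[2] / 3))
  gpos <- place_intervals(Lr, glens, min_gap = 1500L, edge = 800L)
  gstrand <- sample(c("+", "-"), cfg$n_genes, replace = TRUE)
  genes <- data.frame(gene_id = sprintf("gene%02d", seq_len(cfg$n_genes)),
                      start = gpos$start, end = gpos$start + glens - 1L,
                      strand = gstrand, stringsAsFactors = FALSE)
  for (i in seq_len(cfg$n_genes)) {
    ncod <- glens[i] / 3L
    cds <- paste0("ATG",
                  paste(sample(NONSTOP_CODONS, ncod - 2L, replace = TRUE),
                        collapse = ""),
                  "TAA")
    txt <- if (genes$strand[i] == "+") cds else revcomp(cds)
    substr(rec, genes$start[i], genes$end[i]) <- txt
  }

  ## comparators: recipient + neutral noise, no exogenous content -------
  comparators <- vector("list", cfg$comparator_n)
  for (i in seq_len(cfg$comparator_n)) {
    s <- mutate_seq(rec, round(cfg$comparator_sub_rate * Lr))
    nmoves <- sample.int(cfg$comparator_max_moves + 1L, 1L) - 1L
    for (mv in seq_len(nmoves)) {
      cuts <- sort(sample.int(Lr - 1L, 3L))
      s <- paste0(substr(s, 1L, cuts[1]),
                  substr(s, cuts[2] + 1L, cuts[3]),
                  substr(s, cuts[1] + 1L, cuts[2]),
                  substr(s, cuts[3] + 1L, Lr))
    }
    comparators[[i]] <- circular_seq(sprintf("comparator%d", i), s)
  }

  ## donor and chloroplast genomes --------------------------------------
  donor <- random_dna(cfg$donor_len, cfg$gc)
  cp <- random_dna(cfg$cp_len, cfg$cp_gc)
  dsrc <- place_intervals(cfg$donor_len, cfg$donor_segments,
                          min_gap = 100L, edge = 100L)
  csrc <- place_intervals(cfg$cp_len, cfg$cp_segments,
                          min_gap = 100L, edge = 100L)

  ## cybrid base: recipient + coding SNPs + boundary shifts -------------
  cyb <- rec
  shift_gene_idx <- seq_len(length(cfg$boundary_shifts))
  shift_truth <- list()
  for (z in seq_along(cfg$boundary_shifts)) {
    bs <- cfg$boundary_shifts[[z]]
    gi <- shift_gene_idx[z]
    d <- as.integer(bs$len)
    gs <- genes$start[gi]; ge <- genes$end[gi]; gstr <- genes$strand[gi]
    if (bs$end == "5prime") {
      if (d %% 3L != 0L) stop("5' shift length must be a multiple of 3")
      ext <- paste0("ATG",
                    paste(sample(NONSTOP_CODONS, d / 3L - 1L,
                                 replace = TRUE), collapse = ""))
      block <- paste0("TAA", ext)  # in-frame stop bounds the extension
      if (gstr == "+") {
        substr(cyb, gs - d - 3L, gs - 1L) <- block
      } else {
        substr(cyb, ge + 1L, ge + d + 3L) <- revcomp(block)
      }
    } else {
      k <- d %/% 3L
      if (d %% 3L != 0L) stop("3' shift length must be a multiple of 3")
      flank <- paste0(paste(sample(NONSTOP_CODONS, k - 1L, replace = TRUE),
                            collapse = ""), "TAA")
      if (gstr == "+") {
        # disrupt the stop (TAA -> CAA) and write the downstream frame
        substr(cyb, ge - 2L, ge - 2L) <- "C"
        substr(cyb, ge + 1L, ge + d) <- flank
      } else {
        substr(cyb, gs + 2L, gs + 2L) <- "G"  # complement of stop 1st base
        substr(cyb, gs - d, gs - 1L) <- revcomp(flank)
      }
    }
    shift_truth[[z]] <- data.frame(gene_id = genes$gene_id[gi],
                                   end = bs$end, shift_len = d,
                                   stringsAsFactors = FALSE)
  }
  shift_truth <- do.call(rbind, shift_truth)

  snp_genes <- setdiff(seq_len(cfg$n_genes), shift_gene_idx)
  pool <- do.call(rbind, lapply(snp_genes, function(i) {
    len <- genes$end[i] - genes$start[i] + 1L
    data.frame(gene = i, cds_pos = 4:(len - 3L))
  }))
  snp_rows <- list()
  used_codons <- character(0)
  tries <- 0L
  while (length(snp_rows) < cfg$n_coding_snps && tries < 50L * cfg$n_coding_snps) {
    tries <- tries + 1L
    r <- pool[sample.int(nrow(pool), 1L), ]
    ckey <- paste(r$gene, ceiling(r$cds_pos / 3))
    if (ckey %in% used_codons) next
    gi <- r$gene
    gpos2 <- if (genes$strand[gi] == "+") genes$start[gi] + r$cds_pos - 1L
             else genes$end[gi] - r$cds_pos + 1L
    ref_txt <- substr(cyb, gpos2, gpos2)
    ref_cds <- if (genes$strand[gi] == "+") ref_txt else comp_base(ref_txt)
    is_ti <- runif(1) < cfg$titv_bias
    alt_cds <- if (is_ti) {
      c(A = "G", G = "A", C = "T", T = "C")[ref_cds]
    } else {
      sample(setdiff(c("A", "C", "G", "T"),
                     c(ref_cds, c(A = "G", G = "A", C = "T", T = "C")[ref_cds])), 1L)
    }
    # joint codon after the substitution; skip if it creates a stop
    ci <- ceiling(r$cds_pos / 3)
    cod_start <- 3L * (ci - 1L) + 1L
    g_cod <- vapply(cod_start:(cod_start + 2L), function(p) {
      gp <- if (genes$strand[gi] == "+") genes$start[gi] + p - 1L
            else genes$end[gi] - p + 1L
      b <- substr(cyb, gp, gp)
      if (genes$strand[gi] == "+") b else comp_base(b)
    }, character(1))
    ref_codon <- paste(g_cod, collapse = "")
    alt_codon <- ref_codon
    substr(alt_codon, r$cds_pos - cod_start + 1L,
           r$cds_pos - cod_start + 1L) <- alt_cds
    if (alt_codon %in% STOP_CODONS) next
    used_codons <- c(used_codons, ckey)
    alt_txt <- if (genes$strand[gi] == "+") alt_cds else comp_base(alt_cds)
    substr(cyb, gpos2, gpos2) <- alt_txt
    ref_aa <- unname(Biostrings::GENETIC_CODE[ref_codon])
    alt_aa <- unname(Biostrings::GENETIC_CODE[alt_codon])
    snp_rows[[length(snp_rows) + 1L]] <- data.frame(
      gene_id = genes$gene_id[gi], cds_pos = r$cds_pos,
      ref_base = ref_cds, alt_base = unname(alt_cds),
      codon_index = ci, ref_aa = ref_aa, alt_aa = alt_aa,
      effect = if (ref_aa == alt_aa) "synonymous" else "non-synonymous",
      snp_type = if (is_ti) "transition" else "transversion",
      stringsAsFactors = FALSE)
  }
  snps <- do.call(rbind, snp_rows)
  if (is.null(snps) || nrow(snps) < cfg$n_coding_snps) {
    stop("capacity error: could not place ", cfg$n_coding_snps,
         " coding SNPs")
  }

  ## block rearrangement -------------------------------------------------
  zones <- data.frame(start = pmax(1L, genes$start - 800L),
                      end = pmin(Lr, genes$end + 800L))
  bps <- integer(0)
  for (try in seq_len(5000L)) {
    cand <- sort(c(1L, sample.int(Lr - 1L, cfg$n_blocks - 1L) + 1L))
    if (anyDuplicated(cand)) next
    if (any(diff(c(cand, Lr)) < 2000L)) next
    if (any(vapply(cand[-1L], in_zones, logical(1), zones = zones))) next
    bps <- cand; break
  }
  if (!length(bps)) stop("capacity error: could not place block breakpoints")
  blocks <- data.frame(block_id = seq_len(cfg$n_blocks),
                       rec_start = bps,
                       rec_end = c(bps[-1L] - 1L, Lr))
  # draw a permutation/inversion set under which every mediating repeat
  # can flank the breakpoints of a distinct separated recipient adjacency
  nb <- cfg$n_blocks
  sr_assign <- NULL
  for (ptry in seq_len(200L)) {
    perm <- sample.int(nb)
    if (nb > 1L && all(perm == seq_len(nb))) next
    inv <- if (cfg$n_inversions > 0L) sample(perm, cfg$n_inversions)
           else integer(0)
    blocks$inverted <- blocks$block_id %in% inv
    ord_blocks <- blocks[perm, , drop = FALSE]
    # junction slot z lies after cybrid piece z; slot nb wraps the origin
    rec_end_slot <- function(bid) {
      z <- match(bid, ord_blocks$block_id)
      if (!ord_blocks$inverted[z]) z else if (z == 1L) nb else z - 1L
    }
    rec_start_slot <- function(bid) {
      z <- match(bid, ord_blocks$block_id)
      if (!ord_blocks$inverted[z]) { if (z == 1L) nb else z - 1L } else z
    }
    adj_cand <- sample(seq_len(nb - 1L))
    slot_pairs <- lapply(adj_cand, function(i)
      c(rec_end_slot(i), rec_start_slot(i + 1L)))
    pref <- order(vapply(slot_pairs, function(p) any(p == nb), logical(1)))
    adj_cand <- adj_cand[pref]; slot_pairs <- slot_pairs[pref]
    used_slots <- integer(0)
    assign_ok <- TRUE
    sr_assign <- vector("list", nshort)
    for (z in seq_len(nshort)) {
      picked <- NULL
      for (w in seq_along(adj_cand)) {
        p <- slot_pairs[[w]]
        if (p[1] != p[2] && !any(p %in% used_slots)) { picked <- w; break }
      }
      if (is.null(picked)) { assign_ok <- FALSE; break }
      sr_assign[[z]] <- slot_pairs[[picked]]
      used_slots <- c(used_slots, slot_pairs[[picked]])
      adj_cand <- adj_cand[-picked]; slot_pairs <- slot_pairs[-picked]
    }
    if (assign_ok) break
    sr_assign <- NULL
  }
  if (is.null(sr_assign) && nshort > 0L) {
    stop("capacity error: not enough separated rearrangement junctions ",
         "for ", nshort, " mediating repeats")
  }
  ord_blocks$len <- ord_blocks$rec_end - ord_blocks$rec_start + 1L
  ord_blocks$base_start <- cumsum(c(1L, utils::head(ord_blocks$len, -1L)))
  base <- paste(vapply(seq_len(nrow(ord_blocks)), function(i) {
    s <- substr(cyb, ord_blocks$rec_start[i], ord_blocks$rec_end[i])
    if (ord_blocks$inverted[i]) revcomp(s) else s
  }, character(1)), collapse = "")
  Lb <- nchar(base)

  # map a recipient coordinate to base coordinates (+ orientation)
  rec2base <- function(p) {
    i <- which(ord_blocks$rec_start <= p & ord_blocks$rec_end >= p)[1]
    if (ord_blocks$inverted[i]) {
      list(pos = ord_blocks$base_start[i] + (ord_blocks$rec_end[i] - p),
           flip = TRUE)
    } else {
      list(pos = ord_blocks$base_start[i] + (p - ord_blocks$rec_start[i]),
           flip = FALSE)
    }
  }

  genes_base <- genes
  for (i in seq_len(nrow(genes))) {
    a <- rec2base(genes$start[i]); b <- rec2base(genes$end[i])
    genes_base$start[i] <- min(a$pos, b$pos)
    genes_base$end[i] <- max(a$pos, b$pos)
    if (a$flip) {
      genes_base$strand[i] <- if (genes$strand[i] == "+") "-" else "+"
    }
  }

  ## insertions into the base assembly -----------------------------------
  # junction positions (base coords, insert before)
  junctions <- c(ord_blocks$base_start[-1L], Lb + 1L)
  # forbidden zones in base coords (genes +/- margin)
  zones_b <- data.frame(start = pmax(1L, genes_base$start - 850L),
                        end = pmin(Lb, genes_base$end + 850L))
  pick_point <- function(points_taken, sep, lo = 2L, hi = Lb) {
    for (try in seq_len(5000L)) {
      p <- sample.int(hi - lo + 1L, 1L) + lo - 1L
      if (in_zones(p, zones_b)) next
      if (length(points_taken) && any(abs(p - points_taken) < sep)) next
      return(p)
    }
    stop("capacity error: no room left for insertions")
  }

  ins <- list()   # each: list(pos, frag, tag, aux)
  taken <- junctions  # keep clear of junctions too

  # large repeat: source window inside the base, gene-free
  lr_src <- NA_integer_
  for (try in seq_len(5000L)) {
    p <- sample.int(Lb - cfg$large_repeat_len - 2L, 1L) + 1L
    win <- c(p, p + cfg$large_repeat_len - 1L)
    hitg <- any(zones_b$start <= win[2] & zones_b$end >= win[1])
    hitj <- any(junctions > win[1] & junctions <= win[2])
    if (!hitg && !hitj) { lr_src <- p; break }
  }
  if (is.na(lr_src)) stop("capacity error: no gene-free large-repeat window")
  lr_frag <- substr(base, lr_src, lr_src + cfg$large_repeat_len - 1L)
  # nothing may ever be inserted inside the source window, or the two
  # large-repeat copies would diverge
  zones_b <- rbind(zones_b,
                   data.frame(start = lr_src - cfg$min_insert_sep,
                              end = lr_src + cfg$large_repeat_len - 1L +
                                cfg$min_insert_sep))
  p <- pick_point(taken, cfg$min_insert_sep)
  ins[[length(ins) + 1L]] <- list(pos = p, frag = lr_frag,
                                  tag = "large_repeat_copy2", aux = NULL)
  taken <- c(taken, p)

  # Mediating short repeats: both copies of one repeat flank the two
  # cybrid-side breakpoints of a single recipient adjacency (assigned
  # with the permutation above), so the repeat "explains" that
  # rearrangement junction.
  short_truth <- list()
  for (z in seq_len(nshort)) {
    p <- sr_assign[[z]]
    len <- cfg$short_repeats$len[z]
    idn <- cfg$short_repeats$identity[z]
    rs <- random_dna(len, cfg$gc)
    rs2 <- mutate_seq(rs, round((1 - idn) * len))
    ins[[length(ins) + 1L]] <- list(pos = junctions[p[1]], frag = rs,
                                    tag = sprintf("short_repeat%d_copy1", z))
    ins[[length(ins) + 1L]] <- list(pos = junctions[p[2]], frag = rs2,
                                    tag = sprintf("short_repeat%d_copy2", z))
    short_truth[[z]] <- data.frame(repeat_id = z, len = len,
                                   identity = idn,
                                   junction1 = p[1], junction2 = p[2])
  }
  short_truth <- if (nshort) do.call(rbind, short_truth) else
    data.frame(repeat_id = integer(0), len = integer(0),
               identity = numeric(0), junction1 = integer(0),
               junction2 = integer(0))

  # donor segments
  for (z in seq_along(cfg$donor_segments)) {
    p <- pick_point(taken, cfg$min_insert_sep)
    taken <- c(taken, p)
    frag <- substr(donor, dsrc$start[z], dsrc$end[z])
    ins[[length(ins) + 1L]] <- list(pos = p, frag = frag,
                                    tag = sprintf("donor%d", z),
                                    aux = c(dsrc$start[z], dsrc$end[z]))
  }
  # chloroplast segments
  for (z in seq_along(cfg$cp_segments)) {
    p <- pick_point(taken, cfg$min_insert_sep)
    taken <- c(taken, p)
    frag <- mutate_seq(substr(cp, csrc$start[z], csrc$end[z]),
                       round((1 - cfg$cp_identity) * cfg$cp_segments[z]))
    ins[[length(ins) + 1L]] <- list(pos = p, frag = frag,
                                    tag = sprintf("cp%d", z),
                                    aux = c(csrc$start[z], csrc$end[z]))
  }

  ## splice the insertions (descending positions keep earlier ones fixed)
  ord <- order(vapply(ins, `[[`, numeric(1), "pos"), decreasing = TRUE)
  final <- base
  for (i in ord) {
    p <- ins[[i]]$pos
    final <- paste0(substr(final, 1L, p - 1L), ins[[i]]$frag,
                    substr(final, p, nchar(final)))
  }
  # final coordinates of each insertion and shift for base coordinates
  pos_all <- vapply(ins, `[[`, numeric(1), "pos")
  len_all <- vapply(ins, function(x) nchar(x$frag), numeric(1))
  ins_final <- data.frame(
    tag = vapply(ins, `[[`, character(1), "tag"),
    start = as.integer(pos_all + vapply(pos_all, function(p)
      sum(len_all[pos_all < p]), numeric(1))),
    length = as.integer(len_all),
    src_start = vapply(ins, function(x)
      if (is.null(x$aux)) NA_integer_ else as.integer(x$aux[1]), integer(1)),
    src_end = vapply(ins, function(x)
      if (is.null(x$aux)) NA_integer_ else as.integer(x$aux[2]), integer(1)),
    stringsAsFactors = FALSE)
  ins_final$end <- ins_final$start + ins_final$length - 1L

  base2final <- function(p) as.integer(p + sum(len_all[pos_all <= p]))

  genes_final <- genes_base
  genes_final$start <- vapply(genes_base$start, base2final, integer(1))
  genes_final$end <- vapply(genes_base$end, base2final, integer(1))

  lr1_start <- base2final(lr_src)
  lr2_start <- ins_final$start[ins_final$tag == "large_repeat_copy2"]
  s1 <- min(lr1_start, lr2_start); s2 <- max(lr1_start, lr2_start)
  lr_pair <- data.frame(kind = "direct",
                        start1 = s1, end1 = s1 + cfg$large_repeat_len - 1L,
                        start2 = s2, end2 = s2 + cfg$large_repeat_len - 1L,
                        rep_len = cfg$large_repeat_len, identity = 1,
                        stringsAsFactors = FALSE)

  grab <- function(prefix) {
    d <- ins_final[grepl(paste0("^", prefix, "[0-9]+$"), ins_final$tag), ]
    d <- d[order(d$start), , drop = FALSE]
    rownames(d) <- NULL
    d
  }
  truth <- list(genes_recipient = genes, genes_cybrid = genes_final,
                blocks = blocks, block_order = perm,
                snps = snps, boundary_shifts = shift_truth,
                donor_segments = grab("donor")[, c("tag", "start", "end",
                                                   "length", "src_start",
                                                   "src_end")],
                cp_segments = grab("cp")[, c("tag", "start", "end",
                                             "length", "src_start",
                                             "src_end")],
                large_repeat = lr_pair,
                short_repeats = short_truth,
                short_repeat_copies = {
                  d <- ins_final[grepl("^short_repeat", ins_final$tag),
                                 c("tag", "start", "end", "length")]
                  rownames(d) <- NULL
                  d
                })

  structure(list(
    recipient = circular_seq("recipient", rec),
    comparators = comparators,
    donor = circular_seq("donor", donor, circular = FALSE),
    cp = circular_seq("chloroplast", cp),
    cybrid = circular_seq("cybrid", final),
    truth = truth, config = cfg), class = "cybrid_sim")
}

#' @export
print.cybrid_sim <- function(x, ...) {
  cat(sprintf(paste0("<cybrid_sim> cybrid %d bp; %d comparators; ",
                     "%d donor + %d cp segments; %d SNPs planted\n"),
              x$cybrid$length, length(x$comparators),
              nrow(x$truth$donor_segments), nrow(x$truth$cp_segments),
              nrow(x$truth$snps)))
  invisible(x)
}

#' Score recovery of called features against the simulator truth
#'
#' A called feature matches a truth feature when their reciprocal
#' overlap is at least \code{min_reciprocal} and both boundary errors
#' are within \code{boundary_tol}.  Each called feature matches at most
#' one truth feature.
#'
#' @param called data.frame with \code{start}, \code{end}.
#' @param truth data.frame with \code{start}, \code{end}.
#' @param boundary_tol boundary tolerance in bp (default 100).
#' @param min_reciprocal minimum reciprocal overlap (default 0.8).
#' @return list(precision, recall, mean_boundary_error, n_called,
#'   n_truth, n_matched).
#' @export
score_recovery <- function(called, truth, boundary_tol = 100L,
                           min_reciprocal = 0.8) {
  nc <- nrow(called); nt <- nrow(truth)
  used <- logical(nc)
  berr <- numeric(0)
  matched <- 0L
  for (i in seq_len(nt)) {
    best <- 0L; bestov <- 0
    for (j in seq_len(nc)) {
      if (used[j]) next
      ov <- min(truth$end[i], called$end[j]) -
            max(truth$start[i], called$start[j]) + 1L
      if (ov <= 0L) next
      lt <- truth$end[i] - truth$start[i] + 1L
      lc <- called$end[j] - called$start[j] + 1L
      rec_ov <- min(ov / lt, ov / lc)
      e1 <- abs(truth$start[i] - called$start[j])
      e2 <- abs(truth$end[i] - called$end[j])
      if (rec_ov >= min_reciprocal && e1 <= boundary_tol &&
          e2 <= boundary_tol && rec_ov > bestov) {
        best <- j; bestov <- rec_ov
      }
    }
    if (best > 0L) {
      used[best] <- TRUE
      matched <- matched + 1L
      berr <- c(berr, abs(truth$start[i] - called$start[best]),
                abs(truth$end[i] - called$end[best]))
    }
  }
  list(precision = if (nc) matched / nc else NA_real_,
       recall = if (nt) matched / nt else NA_real_,
       mean_boundary_error = if (length(berr)) mean(berr) else NA_real_,
       n_called = nc, n_truth = nt, n_matched = matched)
}
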