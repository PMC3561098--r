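# Gene-level comparisons: SNP calling between orthologous CDSs with
# transition/transversion and synonymous/non-synonymous classification,
# boundary-shift (in-frame 5'/3' extension) detection, six-frame ORF
# finding on circular molecules, Kyte-Doolittle transmembrane-segment
# prediction, and CMS-candidate screening.

STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Translate a CDS with the standard genetic code
#'
#' Plant mitochondria use the standard code (translation table 1).
#' Ambiguous codons translate to \code{X}; stops to \code{*}.
#'
#' @param s nucleotide string, length a multiple of 3.
#' @export
translate_cds <- function(s) {
  s <- toupper(s)
  n <- nchar(s)
  if (n %% 3L != 0L) stop("CDS length ", n, " is not a multiple of 3")
  if (n == 0L) return("")
  starts <- seq.int(1L, n - 2L, 3L)
  codons <- substring(s, starts, starts + 2L)
  aa <- Biostrings::GENETIC_CODE[codons]
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

#' Classify a nucleotide substitution as transition or transversion
#'
#' Transitions exchange purines (A/G) or pyrimidines (C/T); everything
#' else is a transversion.  Vectorised.
#'
#' @param ref,alt single bases in \code{A,C,G,T}.
#' @export
classify_substitution <- function(ref, alt) {
  ref <- toupper(ref); alt <- toupper(alt)
  if (any(!ref %in% c("A", "C", "G", "T")) ||
      !all(alt %in% c("A", "C", "G", "T"))) {
    stop("bases must be one of A, C, G, T")
  }
  if (any(ref == alt)) stop("ref and alt must differ")
  purine <- c("A", "G")
  ifelse((ref %in% purine) == (alt %in% purine), "transition", "transversion")
}

#' Call SNPs between two equal-length orthologous CDSs
#'
#' Substitution-only mode: one record per mismatching position, with the
#' codon translated jointly (all substitutions within a codon applied
#' together) so multi-hit codons are labelled with their joint effect.
#' An internal stop codon before the final one triggers a warning but
#' classification continues.
#'
#' @param ref_cds,alt_cds CDS nucleotide strings, equal length, multiple
#'   of 3.
#' @param gene_id gene label carried into the records.
#' @return data.frame (gene_id, cds_pos, ref_base, alt_base, codon_index,
#'   ref_aa, alt_aa, effect, snp_type).
#' @export
call_gene_snps <- function(ref_cds, alt_cds, gene_id = "gene") {
  ref_cds <- toupper(ref_cds); alt_cds <- toupper(alt_cds)
  if (nchar(ref_cds) != nchar(alt_cds)) {
    stop("CDS lengths differ (", nchar(ref_cds), " vs ", nchar(alt_cds),
         "); indel/extension differences belong to detect_boundary_shift")
  }
  n <- nchar(ref_cds)
  if (n %% 3L != 0L) stop("CDS length is not a multiple of 3")
  rp <- translate_cds(ref_cds); ap <- translate_cds(alt_cds)
  if (grepl("\\*", substr(rp, 1L, nchar(rp) - 1L)) ||
      grepl("\\*", substr(ap, 1L, nchar(ap) - 1L))) {
    warning("internal stop codon in '", gene_id, "'; continuing")
  }
  r <- strsplit(ref_cds, "")[[1]]
  a <- strsplit(alt_cds, "")[[1]]
  pos <- which(r != a)
  if (!length(pos)) {
    return(data.frame(gene_id = character(0), cds_pos = integer(0),
                      ref_base = character(0), alt_base = character(0),
                      codon_index = integer(0), ref_aa = character(0),
                      alt_aa = character(0), effect = character(0),
                      snp_type = character(0), stringsAsFactors = FALSE))
  }
  ci <- ceiling(pos / 3)
  ref_aa <- substring(rp, ci, ci)
  alt_aa <- substring(ap, ci, ci)
  data.frame(gene_id = gene_id, cds_pos = pos,
             ref_base = r[pos], alt_base = a[pos],
             codon_index = as.integer(ci), ref_aa = ref_aa, alt_aa = alt_aa,
             effect = ifelse(ref_aa == alt_aa, "synonymous", "non-synonymous"),
             snp_type = classify_substitution(r[pos], a[pos]),
             stringsAsFactors = FALSE)
}

# codon at an in-frame offset (in codons) from a 1-based genome anchor,
# walking the circle when needed; dir +1 = downstream on the coding strand
codon_at <- function(g, anchor, k, strand) {
  L <- g$length
  if (strand == "+") {
    s <- (anchor - 1L + 3L * k) %% L + 1L
    e <- (s + 2L - 1L) %% L + 1L
    extract_interval(g, interval(s, e, "+"))
  } else {
    s <- (anchor - 1L - 3L * k) %% L + 1L
    e <- (s - 2L - 1L) %% L + 1L
    extract_interval(g, interval(e, s, "-"))
  }
}

# maximal in-frame ATG-led upstream extension length (bp) before the
# first in-frame stop, scanning upstream of a start anchor
upstream_extension <- function(g, start_pos, strand, max_codons = 2000L) {
  best <- 0L
  for (k in seq_len(max_codons)) {
    cod <- codon_at(g, start_pos, -k, strand)
    if (cod %in% STOP_CODONS) break
    if (cod == "ATG") best <- 3L * k
  }
  best
}

#' Detect 5'/3' boundary shifts of a gene between two genomes
#'
#' The reference CDS is located in the alternate genome by a local match
#' of its core (>= \code{min_core_identity}); from the matched core the
#' detector scans in frame.  A 3' extension is reported when the
#' orthologous stop codon is disrupted and the next in-frame stop lies k
#' codons downstream (\code{shift_len = 3k}).  A 5' extension is
#' reported when the alternate genome carries a longer in-frame
#' ATG-initiated extension upstream of the orthologous start (no
#' intervening stop) than the reference genome does.
#'
#' @param ref_model a \code{\link{gene_model}} (single-exon) on the
#'   reference genome.
#' @param ref_genome,alt_genome \code{\link{circular_seq}} objects.
#' @param min_core_identity identity needed to anchor the core CDS.
#' @param max_scan_codons scan limit in codons.
#' @param ... further aligner parameters.
#' @return data.frame (gene_id, end, shift_len, new_start, new_end,
#'   strand); zero rows when the boundaries are conserved.
#' @export
detect_boundary_shift <- function(ref_model, ref_genome, alt_genome,
                                  min_core_identity = 0.9,
                                  max_scan_codons = 2000L, ...) {
  ref_genome <- as_circular_seq(ref_genome, "ref")
  alt_genome <- as_circular_seq(alt_genome, "alt")
  ivs <- ref_model$intervals
  if (nrow(ivs) != 1L) stop("single-exon gene models only")
  ref_strand <- ivs$strand[1]
  cds <- extract_interval(ref_genome,
                          interval(ivs$start[1], ivs$end[1], ref_strand))
  clen <- nchar(cds)
  m <- as.data.frame(find_local_matches(
    circular_seq(ref_model$gene_id, cds, circular = FALSE), alt_genome,
    min_len = max(50L, floor(0.5 * clen)),
    min_identity = min_core_identity, ...))
  if (!nrow(m)) stop("core CDS of '", ref_model$gene_id,
                     "' not found in the alternate genome")
  m <- m[which.max(m$score), ]
  La <- alt_genome$length
  if (m$strand == "+") {
    alt_strand <- "+"
    alt_start <- (m$t_start - (m$q_start - 1L) - 1L) %% La + 1L
    alt_end <- (alt_start - 1L + clen - 1L) %% La + 1L
  } else {
    alt_strand <- "-"
    alt_end_coord <- (m$t_end + (m$q_start - 1L) - 1L) %% La + 1L  # CDS 5' end
    alt_start <- alt_end_coord
    alt_end <- (alt_start - 1L - (clen - 1L)) %% La + 1L
  }
  # on the coding strand: position of the first base of the CDS and of
  # the first base of the stop codon
  anchor5 <- alt_start
  anchor_stop <- if (alt_strand == "+") {
    (alt_start - 1L + clen - 3L) %% La + 1L
  } else {
    (alt_start - 1L - (clen - 3L)) %% La + 1L
  }
  out <- list()
  # 3' side
  stop_cod <- codon_at(alt_genome, anchor_stop, 0L, alt_strand)
  if (!stop_cod %in% STOP_CODONS) {
    for (k in seq_len(max_scan_codons)) {
      if (codon_at(alt_genome, anchor_stop, k, alt_strand) %in% STOP_CODONS) {
        out[[length(out) + 1L]] <- data.frame(
          gene_id = ref_model$gene_id, end = "3prime", shift_len = 3L * k,
          stringsAsFactors = FALSE)
        break
      }
    }
  }
  # 5' side
  e_alt <- upstream_extension(alt_genome, anchor5, alt_strand, max_scan_codons)
  e_ref <- upstream_extension(ref_genome,
                              if (ref_strand == "+") ivs$start[1] else ivs$end[1],
                              ref_strand, max_scan_codons)
  if (e_alt > 0L && e_alt > e_ref) {
    out[[length(out) + 1L]] <- data.frame(
      gene_id = ref_model$gene_id, end = "5prime", shift_len = e_alt,
      stringsAsFactors = FALSE)
  }
  if (!length(out)) {
    return(data.frame(gene_id = character(0), end = character(0),
                      shift_len = integer(0), new_start = integer(0),
                      new_end = integer(0), strand = character(0),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res$new_start <- NA_integer_; res$new_end <- NA_integer_
  for (i in seq_len(nrow(res))) {
    d5 <- if (res$end[i] == "5prime") res$shift_len[i] else 0L
    d3 <- if (res$end[i] == "3prime") res$shift_len[i] else 0L
    if (alt_strand == "+") {
      res$new_start[i] <- (alt_start - 1L - d5) %% La + 1L
      res$new_end[i] <- (alt_end - 1L + d3) %% La + 1L
    } else {
      res$new_start[i] <- (alt_start - 1L + d5) %% La + 1L
      res$new_end[i] <- (alt_end - 1L - d3) %% La + 1L
    }
  }
  res$strand <- alt_strand
  rownames(res) <- NULL
  res
}

# vectorised single-strand ORF scan of a (possibly doubled) string;
# returns 1-based [start, end] of ATG..stop spans, stop included
scan_orf_frames <- function(s, min_len) {
  n <- nchar(s)
  out <- list()
  for (f in 1:3) {
    if (n - f + 1L < 6L) next
    starts <- seq.int(f, n - 2L, 3L)
    codons <- substring(s, starts, starts + 2L)
    is_stop <- codons %in% STOP_CODONS
    is_atg <- codons == "ATG"
    if (!any(is_stop) || !any(is_atg)) next
    seg <- cumsum(c(0L, utils::head(is_stop, -1L)))
    atg_idx <- which(is_atg)
    first_atg <- tapply(atg_idx, seg[atg_idx], min)
    stop_idx <- which(is_stop)
    sk <- as.character(seg[stop_idx])
    fa <- first_atg[sk]
    ok <- !is.na(fa)
    a <- as.integer(fa[ok]); st <- stop_idx[ok]
    len <- (st - a + 1L) * 3L
    keep <- len >= min_len
    if (any(keep)) {
      out[[length(out) + 1L]] <- data.frame(start = starts[a[keep]],
                                            end = starts[st[keep]] + 2L,
                                            length = len[keep])
    }
  }
  if (!length(out)) {
    return(data.frame(start = integer(0), end = integer(0),
                      length = integer(0)))
  }
  do.call(rbind, out)
}

#' Find open reading frames in all six frames
#'
#' ATG-to-stop spans (stop codon included in the length) on both strands;
#' for each stop only the longest ORF is reported.  On a circular
#' molecule ORFs crossing the origin are included once, flagged
#' \code{wraps}.
#'
#' @param g a \code{\link{circular_seq}}.
#' @param min_orf_len minimum ORF length in bp, stop included
#'   (default 300).
#' @return data.frame (orf_id, start, end, strand, length, wraps,
#'   protein, seq), sorted by start.
#' @export
find_orfs <- function(g, min_orf_len = 300L) {
  g <- as_circular_seq(g, "g")
  L <- g$length
  res <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") g$seq else revcomp(g$seq)
    sc <- if (g$circular) paste0(s, s) else s
    orf <- scan_orf_frames(sc, min_orf_len)
    if (g$circular) {
      orf <- orf[orf$start <= L & orf$length <= L, , drop = FALSE]
    }
    if (!nrow(orf)) next
    if (strand == "+") {
      st <- orf$start
      en <- (orf$end - 1L) %% L + 1L
    } else {
      # map from reverse-complement coordinates back to the genome; a
      # wrapped ORF keeps start > end
      st <- L - ((orf$end - 1L) %% L + 1L) + 1L
      en <- L - orf$start + 1L
    }
    wraps <- g$circular & orf$end > L
    res[[length(res) + 1L]] <- data.frame(
      start = st, end = en, strand = strand, length = orf$length,
      wraps = wraps, stringsAsFactors = FALSE)
  }
  if (!length(res)) {
    return(data.frame(orf_id = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      length = integer(0), wraps = logical(0),
                      protein = character(0), seq = character(0),
                      stringsAsFactors = FALSE))
  }
  df <- do.call(rbind, res)
  # orf coordinates on the genome: for '-' strand start/end refer to the
  # genome (start < end unless wrapping); the 5' end is at 'end'
  df <- df[order(df$start, df$end, df$strand), , drop = FALSE]
  seqs <- character(nrow(df))
  prots <- character(nrow(df))
  for (i in seq_len(nrow(df))) {
    iv <- interval(df$start[i], df$end[i], df$strand[i])
    seqs[i] <- extract_interval(g, iv)
    prots[i] <- substr(translate_cds(seqs[i]), 1L, df$length[i] / 3L - 1L)
  }
  out <- data.frame(orf_id = paste0("orf", df$length - 3L, "_", seq_len(nrow(df))),
                    start = df$start, end = df$end, strand = df$strand,
                    length = df$length, wraps = df$wraps,
                    protein = prots, seq = seqs, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

# Kyte-Doolittle hydropathy index
KD_SCALE <- c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5,
              E = -3.5, G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9,
              M = 1.9, F = 2.8, P = -1.6, S = -0.8, T = -0.7, W = -0.9,
              Y = -1.3, V = 4.2)

#' Predict transmembrane segments by Kyte-Doolittle hydropathy
#'
#' Mean hydropathy over a sliding window; maximal runs of windows above
#' the threshold are merged and reported as candidate membrane-spanning
#' segments (residue coordinates).
#'
#' @param protein amino-acid string (standard 20 letters).
#' @param window window size in residues (default 19).
#' @param threshold mean-hydropathy threshold (default 1.6).
#' @return data.frame (start, end, length, max_score).
#' @export
predict_tm_segments <- function(protein, window = 19L, threshold = 1.6) {
  protein <- toupper(protein)
  aa <- strsplit(protein, "")[[1]]
  if (any(!aa %in% names(KD_SCALE))) {
    stop("non-standard amino acid in protein: ",
         paste(unique(aa[!aa %in% names(KD_SCALE)]), collapse = ","))
  }
  n <- length(aa)
  empty <- data.frame(start = integer(0), end = integer(0),
                      length = integer(0), max_score = numeric(0))
  if (n < window) return(empty)
  h <- KD_SCALE[aa]
  cs <- c(0, cumsum(h))
  wm <- (cs[(window + 1L):(n + 1L)] - cs[1:(n - window + 1L)]) / window
  above <- wm > threshold
  if (!any(above)) return(empty)
  r <- rle(above)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  idx <- which(r$values)
  segs <- data.frame(start = starts[idx],
                     end = ends[idx] + window - 1L)
  segs$length <- segs$end - segs$start + 1L
  segs$max_score <- vapply(seq_len(nrow(segs)), function(i) {
    max(wm[starts[idx[i]]:ends[idx[i]]])
  }, numeric(1))
  segs
}

# circular distance between two intervals (0 when they overlap)
circ_iv_dist <- function(s1, e1, s2, e2, L) {
  if (max(s1, s2) <= min(e1, e2)) return(0L)
  d <- c(abs(s2 - e1), abs(s1 - e2))
  d <- c(d, L - d)
  min(d)
}

#' Screen ORFs for CMS-candidate features
#'
#' Ranks ORFs by three binary criteria characteristic of cytoplasmic
#' male sterility genes: unique to the focal mitotype, carrying a
#' predicted membrane-spanning segment, and lying near an annotated
#' functional gene.
#'
#' @param orfs ORF table with a \code{sharedness} column (see
#'   \code{\link{classify_orf_sharedness}}).
#' @param genes data.frame of annotated genes (\code{start, end}).
#' @param L genome length (for circular distances).
#' @param proximity maximum distance to a functional gene in bp
#'   (default 2000).
#' @param tm_window,tm_threshold hydropathy parameters.
#' @return the ORF table with criterion columns \code{is_unique},
#'   \code{has_tm}, \code{near_gene} and \code{n_criteria}, ranked by
#'   \code{n_criteria} descending.
#' @export
screen_cms_candidates <- function(orfs, genes, L, proximity = 2000L,
                                  tm_window = 19L, tm_threshold = 1.6) {
  n <- nrow(orfs)
  if (is.null(orfs$sharedness)) stop("run classify_orf_sharedness first")
  is_unique <- orfs$sharedness == "unique"
  has_tm <- vapply(orfs$protein, function(p) {
    nchar(p) >= tm_window &&
      nrow(predict_tm_segments(p, tm_window, tm_threshold)) > 0L
  }, logical(1), USE.NAMES = FALSE)
  near_gene <- vapply(seq_len(n), function(i) {
    if (!nrow(genes)) return(FALSE)
    any(vapply(seq_len(nrow(genes)), function(j) {
      circ_iv_dist(orfs$start[i], orfs$end[i],
                   genes$start[j], genes$end[j], L) <= proximity
    }, logical(1)))
  }, logical(1))
  orfs$is_unique <- is_unique
  orfs$has_tm <- has_tm
  orfs$near_gene <- near_gene
  orfs$n_criteria <- is_unique + has_tm + near_gene
  orfs[order(-orfs$n_criteria, orfs$start), , drop = FALSE]
}
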