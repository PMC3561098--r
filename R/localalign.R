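# Seeded local-similarity engine.  One aligner (exact k-mer seeds merged
# along diagonals, X-drop ungapped extension, co-linear chaining, banded
# gapped rescoring) is used for every similarity search in the package so
# "similarity" means the same thing in every stage: identical columns
# divided by alignment columns, gap columns counting against.

#' Optimal global alignment of two short sequences
#'
#' Exhaustive dynamic programming under unit scores (quadratic time and
#' memory; use \code{\link{find_local_matches}} for genome-scale input).
#' Tie-breaking is deterministic: a diagonal step (match or mismatch) is
#' preferred over a gap, and a gap in \code{b} over a gap in \code{a}.
#'
#' @param a,b nucleotide strings.
#' @param match,mismatch,gap unit scores (defaults +1/-1/-2).
#' @param max_len size cap on either input (default 20 kb).
#' @return list with \code{score}, \code{aln_len}, \code{matches},
#'   \code{identity} and the aligned strings \code{a_aln}, \code{b_aln}.
#' @export
align_pair <- function(a, b, match = 1L, mismatch = -1L, gap = -2L,
                       max_len = 20000L) {
  a <- toupper(a); b <- toupper(b)
  if (nchar(a) > max_len || nchar(b) > max_len) {
    stop("align_pair input exceeds the ", max_len,
         " bp cap; use find_local_matches for long sequences")
  }
  cpp_global_align(a, b, match, mismatch, gap)
}

# Greedy co-linear chaining of ungapped segments (all in ascending
# coordinates on both axes).  seg is a data.frame qs,qe,ts,te,matches.
chain_segments <- function(seg, chain_gap, max_overlap = 30L) {
  n <- nrow(seg)
  if (n == 0L) return(integer(0))
  o <- order(seg$qs, seg$ts)
  seg <- seg[o, ]
  chain <- integer(n)        # chain id per (sorted) segment
  open_qe <- integer(0); open_te <- integer(0); open_id <- integer(0)
  nxt <- 0L
  for (i in seq_len(n)) {
    qs <- seg$qs[i]; ts <- seg$ts[i]
    # retire chains that can no longer accept members
    if (length(open_id)) {
      live <- open_qe >= qs - chain_gap - 1L
      open_qe <- open_qe[live]; open_te <- open_te[live]; open_id <- open_id[live]
    }
    pick <- 0L
    if (length(open_id)) {
      qgap <- qs - open_qe - 1L
      tgap <- ts - open_te - 1L
      ok <- qgap >= -max_overlap & qgap <= chain_gap &
            tgap >= -max_overlap & tgap <= chain_gap &
            abs(qgap - tgap) <= chain_gap
      if (any(ok)) {
        cand <- which(ok)
        pick <- cand[which.min(abs(qgap[cand] - tgap[cand]))]
      }
    }
    if (pick > 0L) {
      chain[i] <- open_id[pick]
      open_qe[pick] <- max(open_qe[pick], seg$qe[i])
      open_te[pick] <- max(open_te[pick], seg$te[i])
    } else {
      nxt <- nxt + 1L
      chain[i] <- nxt
      open_qe <- c(open_qe, seg$qe[i])
      open_te <- c(open_te, seg$te[i])
      open_id <- c(open_id, nxt)
    }
  }
  ids <- integer(n); ids[o] <- chain
  ids
}

# One orientation of the search: q and t as given, coordinates ascending.
# Returns chained, banded-rescored matches as a data.frame.
matches_one_strand <- function(q, t, seed_k, chain_gap, xdrop, max_occ,
                               match, mismatch, gap, band_pad = 16L,
                               drop_diag_mod = NA_integer_) {
  seg <- cpp_seed_segments(q, t, seed_k, chain_gap, xdrop, max_occ)
  if (nrow(seg) == 0L) return(NULL)
  if (!is.na(drop_diag_mod)) {
    keep <- ((seg$qs - seg$ts) %% drop_diag_mod) != 0L
    seg <- seg[keep, , drop = FALSE]
    if (nrow(seg) == 0L) return(NULL)
  }
  seg$chain <- chain_segments(seg, chain_gap)
  out <- vector("list", max(seg$chain))
  for (cid in unique(seg$chain)) {
    sc <- seg[seg$chain == cid, , drop = FALSE]
    qs <- min(sc$qs); qe <- max(sc$qe)
    ts <- min(sc$ts); te <- max(sc$te)
    dloc <- (sc$ts - ts) - (sc$qs - qs)
    band_lo <- min(dloc) - band_pad
    band_hi <- max(dloc) + band_pad
    al <- cpp_banded_align(substr(q, qs, qe), substr(t, ts, te),
                           band_lo, band_hi, match, mismatch, gap)
    out[[cid]] <- data.frame(q_start = qs, q_end = qe, t_start = ts, t_end = te,
                             identity = al$identity, aln_len = al$aln_len,
                             matches = al$matches, score = al$score)
  }
  do.call(rbind, out)
}

#' Find local similarity matches between two genomes
#'
#' Exact \code{seed_k}-mer seeds are collected on both strands, merged
#' along diagonals, extended ungapped under an X-drop, chained when
#' co-linear within \code{chain_gap}, and each chain is rescored by banded
#' global alignment over its full span.  A circular query is searched
#' through a doubled view so matches may cross the origin; duplicates
#' whose start lies beyond L are removed.  When query and target are the
#' same sequence, the trivial self-diagonal is suppressed.
#'
#' @param query,target \code{\link{circular_seq}} objects (or strings,
#'   taken as linear).
#' @param min_len minimum alignment length (columns) of a reported match.
#' @param min_identity minimum identity (matching columns / columns).
#' @param seed_k exact seed length (>= 8).
#' @param chain_gap maximum gap bridged inside one match.
#' @param xdrop ungapped-extension drop-off.
#' @param match,mismatch,gap unit scores.
#' @param max_occ seeds occurring more often than this in the target are
#'   skipped (repeat masking).
#' @param self force or suppress self-comparison handling.  \code{NULL}
#'   (default) treats the comparison as a self-comparison when query and
#'   target are the same object (id and sequence); in a self-comparison
#'   the trivial identity diagonal is suppressed.  Callers comparing two
#'   genomes that may be coincidentally identical should pass
#'   \code{FALSE}.
#' @return data.frame with columns \code{query, q_start, q_end, target,
#'   t_start, t_end, strand, identity, aln_len, score}; a match wrapping
#'   the query origin has \code{q_start > q_end}.
#' @export
find_local_matches <- function(query, target, min_len = 100L,
                               min_identity = 0.7, seed_k = 12L,
                               chain_gap = 100L, xdrop = 20L,
                               match = 1L, mismatch = -1L, gap = -2L,
                               max_occ = 256L, self = NULL) {
  stopifnot(seed_k >= 8L, min_len >= seed_k)
  query <- as_circular_seq(query, id = "query", circular = FALSE)
  target <- as_circular_seq(target, id = "target", circular = FALSE)
  if (query$length == 0L || target$length == 0L) stop("empty sequence")
  L <- query$length
  Lt <- target$length
  if (is.null(self)) {
    self <- identical(query$seq, target$seq) && identical(query$id, target$id)
  }

  qseq <- query$seq
  doubled <- isTRUE(query$circular) && L > seed_k
  if (doubled) qseq <- paste0(qseq, qseq)

  res <- list()
  fwd <- matches_one_strand(qseq, target$seq, seed_k, chain_gap, xdrop,
                            max_occ, match, mismatch, gap,
                            drop_diag_mod = if (self) L else NA_integer_)
  if (!is.null(fwd)) { fwd$strand <- "+"; res[[length(res) + 1L]] <- fwd }
  trc <- revcomp(target$seq)
  rev <- matches_one_strand(qseq, trc, seed_k, chain_gap, xdrop,
                            max_occ, match, mismatch, gap)
  if (!is.null(rev)) {
    # map coordinates back from the reverse-complemented target
    ts <- Lt - rev$t_end + 1L
    te <- Lt - rev$t_start + 1L
    rev$t_start <- ts; rev$t_end <- te
    rev$strand <- "-"
    res[[length(res) + 1L]] <- rev
  }
  m <- if (length(res)) do.call(rbind, res) else
    data.frame(q_start = integer(0), q_end = integer(0), t_start = integer(0),
               t_end = integer(0), identity = numeric(0), aln_len = integer(0),
               matches = integer(0), score = integer(0), strand = character(0))

  if (nrow(m)) {
    if (doubled) {
      m <- m[m$q_start <= L, , drop = FALSE]
      m <- m[(m$q_end - m$q_start + 1L) <= L, , drop = FALSE]
    }
    if (self) {
      # suppress residual trivial overlaps of the identity diagonal
      triv <- m$strand == "+" & m$q_start == m$t_start & m$q_end == m$t_end
      m <- m[!triv, , drop = FALSE]
    }
    m <- m[m$aln_len >= min_len & m$identity >= min_identity, , drop = FALSE]
    if (nrow(m) && doubled) {
      m$q_end <- ifelse(m$q_end > L, m$q_end - L, m$q_end)
    }
    m <- m[order(m$q_start, m$t_start, m$strand), , drop = FALSE]
  }
  rownames(m) <- NULL
  out <- data.frame(query = rep(query$id, nrow(m)),
                    q_start = as.integer(m$q_start),
                    q_end = as.integer(m$q_end), target = rep(target$id, nrow(m)),
                    t_start = as.integer(m$t_start),
                    t_end = as.integer(m$t_end),
                    strand = as.character(m$strand),
                    identity = as.numeric(m$identity),
                    aln_len = as.integer(m$aln_len),
                    score = as.integer(m$score),
                    stringsAsFactors = FALSE)
  class(out) <- c("local_matches", "data.frame")
  out
}

#' Write a match table as TSV
#'
#' @param m data.frame of matches.
#' @param path output file.
#' @export
write_matches_tsv <- function(m, path) {
  write_stage_tsv(as.data.frame(m), path)
}
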