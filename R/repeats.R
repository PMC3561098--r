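# Repeat detection within one genome by self-comparison: large repeat
# pairs (the recombination substrate behind multipartite genome
# structure) and short direct/inverted repeats, with genome-fraction
# accounting.  Repeats are counted as PAIRS of disjoint copies; tandem
# (self-overlapping) hits are excluded.

repeat_pair_df <- function() {
  data.frame(kind = character(0), start1 = integer(0), end1 = integer(0),
             start2 = integer(0), end2 = integer(0), rep_len = integer(0),
             identity = numeric(0), stringsAsFactors = FALSE)
}

# Self-comparison -> canonical disjoint pairs (copy 1 precedes copy 2).
self_pairs <- function(g, min_len, min_identity, seed_k, ...) {
  g <- as_circular_seq(g, "g")
  m <- find_local_matches(g, g, min_len = min_len, min_identity = min_identity,
                          seed_k = seed_k, self = TRUE, ...)
  m <- as.data.frame(m)
  if (nrow(m) == 0L) return(repeat_pair_df())
  # drop matches wrapping the origin on the query side: their partner copy
  # is reported from the other role of the symmetric self-comparison
  m <- m[m$q_end >= m$q_start, , drop = FALSE]
  if (nrow(m) == 0L) return(repeat_pair_df())
  # disjoint copies only (tandem/self-overlapping hits excluded)
  disj <- m$q_end < m$t_start | m$t_end < m$q_start
  m <- m[disj, , drop = FALSE]
  if (nrow(m) == 0L) return(repeat_pair_df())
  s1 <- pmin(m$q_start, m$t_start); e1 <- ifelse(m$q_start <= m$t_start, m$q_end, m$t_end)
  s2 <- pmax(m$q_start, m$t_start); e2 <- ifelse(m$q_start <= m$t_start, m$t_end, m$q_end)
  pr <- data.frame(kind = ifelse(m$strand == "+", "direct", "inverted"),
                   start1 = s1, end1 = e1, start2 = s2, end2 = e2,
                   rep_len = m$aln_len, identity = m$identity,
                   stringsAsFactors = FALSE)
  # each pair is seen from both roles of the self-comparison: deduplicate
  key <- paste(pr$kind, pr$start1, pr$end1, pr$start2, pr$end2)
  pr <- pr[!duplicated(key), , drop = FALSE]
  # near-duplicates from slightly different extensions of the two roles
  pr <- pr[order(-pr$rep_len), , drop = FALSE]
  keep <- rep(TRUE, nrow(pr))
  if (nrow(pr) > 1L) {
    for (i in 2:nrow(pr)) {
      for (j in which(keep[seq_len(i - 1L)])) {
        if (pr$kind[i] == pr$kind[j] &&
            abs(pr$start1[i] - pr$start1[j]) <= 20L &&
            abs(pr$start2[i] - pr$start2[j]) <= 20L) { keep[i] <- FALSE; break }
      }
    }
  }
  pr <- pr[keep, , drop = FALSE]
  pr <- pr[order(pr$start1, pr$start2), , drop = FALSE]
  rownames(pr) <- NULL
  pr
}

#' Find short repeats (direct and inverted) in a genome
#'
#' Self-comparison through the seeded aligner; the trivial full-length
#' self-match is suppressed, each qualifying pair of disjoint copies is
#' reported once with copy 1 preceding copy 2 in genome order.
#'
#' @param g a \code{\link{circular_seq}}.
#' @param min_len,max_len repeat length window in bp (defaults 30-500).
#' @param min_identity minimum identity (default 0.90).
#' @param include_inverted also report inverted repeats (default TRUE).
#' @param seed_k seed length; the default 12 resolves repeats down to the
#'   30 bp class.
#' @param ... further aligner parameters.
#' @return data.frame of repeat pairs (kind, start1, end1, start2, end2,
#'   rep_len, identity).
#' @export
find_repeats <- function(g, min_len = 30L, max_len = 500L,
                         min_identity = 0.90, include_inverted = TRUE,
                         seed_k = 12L, ...) {
  stopifnot(min_len <= max_len)
  pr <- self_pairs(g, min_len = min_len, min_identity = min_identity,
                   seed_k = seed_k, chain_gap = 30L, ...)
  pr <- pr[pr$rep_len <= max_len, , drop = FALSE]
  if (!include_inverted) pr <- pr[pr$kind == "direct", , drop = FALSE]
  rownames(pr) <- NULL
  pr
}

#' Find large repeat pairs in a genome
#'
#' As \code{\link{find_repeats}} but with the large-repeat thresholds;
#' pairs are sorted by repeat length, descending.
#'
#' @param g a \code{\link{circular_seq}}.
#' @param large_min minimum repeat length in bp (default 1000, separating
#'   the multi-kb class from the 30-500 bp class).
#' @param min_identity minimum identity (default 0.95).
#' @param ... further aligner parameters.
#' @export
find_large_repeats <- function(g, large_min = 1000L, min_identity = 0.95, ...) {
  pr <- self_pairs(g, min_len = large_min, min_identity = min_identity,
                   seed_k = 12L, ...)
  pr <- pr[order(-pr$rep_len), , drop = FALSE]
  rownames(pr) <- NULL
  pr
}

#' Fraction of the genome covered by short-repeat copies
#'
#' Union of all repeat copy intervals (both copies of every pair), each
#' position counted once, divided by the genome length.
#'
#' @param pairs data.frame of repeat pairs.
#' @param L genome length in bp.
#' @export
short_repeat_fraction <- function(pairs, L) {
  if (nrow(pairs) == 0L) return(0)
  union_span(c(pairs$start1, pairs$start2), c(pairs$end1, pairs$end2), L) / L
}

#' Full repeat catalogue of a genome
#'
#' Convenience wrapper returning large pairs, short pairs and the
#' short-repeat genome fraction together.
#'
#' @param g a \code{\link{circular_seq}}.
#' @param short_min,short_max,short_identity short-repeat thresholds.
#' @param large_min,large_identity large-repeat thresholds.
#' @return object of class \code{RepeatSet}: list(large, short,
#'   short_fraction).
#' @export
repeat_set <- function(g, short_min = 30L, short_max = 500L,
                       short_identity = 0.90, large_min = 1000L,
                       large_identity = 0.95) {
  g <- as_circular_seq(g, "g")
  short <- find_repeats(g, short_min, short_max, short_identity)
  large <- find_large_repeats(g, large_min, large_identity)
  structure(list(large = large, short = short,
                 short_fraction = short_repeat_fraction(short, g$length),
                 L = g$length),
            class = "RepeatSet")
}

#' @export
print.RepeatSet <- function(x, ...) {
  cat(sprintf("<RepeatSet> %d large pair(s), %d short pair(s), short-repeat fraction %.2f%%\n",
              nrow(x$large), nrow(x$short), 100 * x$short_fraction))
  invisible(x)
}
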