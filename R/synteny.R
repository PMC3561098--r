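# Syntenic-region detection between two mitotypes: chained local matches
# filtered by length/identity, resolved to non-overlapping labelled
# regions on the focal genome, with per-genome coverage accounting and
# dot-plot export.

#' Detect syntenic regions between two genomes
#'
#' Local matches from \code{\link{find_local_matches}} (already chained
#' into maximal co-linear runs) are filtered by \code{min_len} and
#' \code{min_identity}; overlapping candidates on genome A are resolved
#' by keeping the higher-scoring region and trimming the other (overlaps
#' up to \code{slack} bp are tolerated).  Regions are labelled S1... in
#' genome-A coordinate order.
#'
#' @param a,b \code{\link{circular_seq}} objects (A is the focal genome).
#' @param min_len minimum region length in bp (default 1000).
#' @param min_identity minimum identity (default 0.95).
#' @param chain_gap co-linear chaining gap passed to the aligner.
#' @param slack tolerated overlap between regions on A, in bp.
#' @param ... further aligner parameters.
#' @return object of class \code{SyntenyMap}: list with \code{regions}
#'   (data.frame label, a_start, a_end, b_start, b_end, orientation,
#'   identity, length), \code{coverage_a}, \code{coverage_b},
#'   \code{L_a}, \code{L_b}.
#' @export
detect_syntenic_regions <- function(a, b, min_len = 1000L,
                                    min_identity = 0.95,
                                    chain_gap = 100L, slack = 50L, ...) {
  a <- as_circular_seq(a, "A"); b <- as_circular_seq(b, "B")
  m <- find_local_matches(a, b, min_len = min_len,
                          min_identity = min_identity,
                          chain_gap = chain_gap, self = FALSE, ...)
  m <- as.data.frame(m)
  # work on non-wrapping spans for the overlap resolution
  m$a_len <- ifelse(m$q_end >= m$q_start, m$q_end - m$q_start + 1L,
                    a$length - m$q_start + 1L + m$q_end)
  m <- m[order(-m$score), , drop = FALSE]
  keep <- logical(nrow(m))
  for (i in seq_len(nrow(m))) {
    if (m$q_end[i] < m$q_start[i]) { keep[i] <- TRUE; next }  # wrapping: keep as-is
    ok <- TRUE
    if (any(keep)) {
      prev <- m[keep & m$q_end >= m$q_start, , drop = FALSE]
      if (nrow(prev)) {
        ov_lo <- pmax(m$q_start[i], prev$q_start)
        ov_hi <- pmin(m$q_end[i], prev$q_end)
        ov <- pmax(0L, ov_hi - ov_lo + 1L)
        for (j in which(ov > slack)) {
          # trim the current (lower-scoring) region away from the overlap
          if (prev$q_start[j] <= m$q_start[i]) {
            cut <- ov[j] - slack
            m$q_start[i] <- m$q_start[i] + cut
            if (m$strand[i] == "+") m$t_start[i] <- m$t_start[i] + cut
            else m$t_end[i] <- m$t_end[i] - cut
          } else {
            cut <- ov[j] - slack
            m$q_end[i] <- m$q_end[i] - cut
            if (m$strand[i] == "+") m$t_end[i] <- m$t_end[i] - cut
            else m$t_start[i] <- m$t_start[i] + cut
          }
        }
        if (m$q_end[i] - m$q_start[i] + 1L < min_len) ok <- FALSE
      }
    }
    keep[i] <- ok
  }
  m <- m[keep, , drop = FALSE]
  m <- m[order(m$q_start), , drop = FALSE]
  regions <- data.frame(
    label = if (nrow(m)) paste0("S", seq_len(nrow(m))) else character(0),
    a_start = m$q_start, a_end = m$q_end,
    b_start = m$t_start, b_end = m$t_end,
    orientation = ifelse(m$strand == "+", "same", "opposite"),
    identity = m$identity,
    length = ifelse(m$q_end >= m$q_start, m$q_end - m$q_start + 1L,
                    a$length - m$q_start + 1L + m$q_end),
    score = m$score,
    stringsAsFactors = FALSE)
  rownames(regions) <- NULL
  sm <- structure(list(regions = regions, L_a = a$length, L_b = b$length,
                       a_id = a$id, b_id = b$id),
                  class = "SyntenyMap")
  sm$coverage_a <- coverage_fraction(sm, "A")
  sm$coverage_b <- coverage_fraction(sm, "B")
  sm
}

#' @export
print.SyntenyMap <- function(x, ...) {
  cat(sprintf("<SyntenyMap> %s vs %s: %d regions, coverage %.2f%% / %.2f%%\n",
              x$a_id, x$b_id, nrow(x$regions),
              100 * x$coverage_a, 100 * x$coverage_b))
  invisible(x)
}

#' Fraction of a genome covered by the syntenic regions
#'
#' Union length of the chosen genome's region intervals (wraparound
#' aware, overlaps counted once) divided by that genome's length.
#'
#' @param m a \code{SyntenyMap}.
#' @param which \code{"A"} or \code{"B"}.
#' @export
coverage_fraction <- function(m, which = c("A", "B")) {
  which <- match.arg(which)
  r <- m$regions
  if (nrow(r) == 0L) return(0)
  if (which == "A") {
    union_span(r$a_start, r$a_end, m$L_a) / m$L_a
  } else {
    union_span(pmin(r$b_start, r$b_end), pmax(r$b_start, r$b_end), m$L_b) / m$L_b
  }
}

#' Dot-plot segment endpoints for a synteny map
#'
#' One segment per region; opposite-orientation regions descend on the B
#' axis (anti-diagonal).
#'
#' @param m a \code{SyntenyMap}.
#' @return data.frame \code{label, a_start, a_end, b_start, b_end,
#'   orientation}.
#' @export
dotplot_points <- function(m) {
  r <- m$regions
  data.frame(label = r$label, a_start = r$a_start, a_end = r$a_end,
             b_start = ifelse(r$orientation == "same", r$b_start, r$b_end),
             b_end = ifelse(r$orientation == "same", r$b_end, r$b_start),
             orientation = r$orientation, stringsAsFactors = FALSE)
}
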