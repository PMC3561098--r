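# Multi-genome comparisons: unique-region calling of a focal genome
# against N comparators (a position is unique only when covered by NO
# comparator), chloroplast-derived (MTPT) segment detection, and ORF
# sharedness classification.

# union of covered focal positions across one comparator's matches
covered_ranges <- function(m, L) {
  m <- as.data.frame(m)
  if (nrow(m) == 0L) return(IRanges::IRanges())
  pieces <- do.call(rbind, Map(iv_pieces, m$q_start, m$q_end,
                               MoreArgs = list(L = L)))
  IRanges::reduce(IRanges::IRanges(start = pieces[, "start"],
                                   end = pmin(pieces[, "end"], L)))
}

#' Call unique regions of a focal genome against comparator genomes
#'
#' Per comparator, the covered set is the union of local-match intervals
#' on the focal genome at deliberately permissive thresholds ("unique"
#' means no appreciable homology at all).  Unique regions are maximal
#' runs of positions covered by no comparator, filtered to
#' \code{min_unique_len}, labelled U1... in coordinate order.  On a
#' circular focal genome the run across the origin is merged.
#'
#' @param focal the focal \code{\link{circular_seq}}.
#' @param comparators list of comparator genomes.
#' @param cover_min_len minimum match length counting as coverage
#'   (default 50 bp).
#' @param cover_min_identity minimum match identity counting as coverage
#'   (default 0.70).
#' @param min_unique_len minimum reported unique-region length
#'   (default 400 bp).
#' @param ... further aligner parameters.
#' @return data.frame (label, start, end, length, wraps) with attributes
#'   \code{fraction_unique} and \code{L}.
#' @export
call_unique_regions <- function(focal, comparators, cover_min_len = 50L,
                                cover_min_identity = 0.70,
                                min_unique_len = 400L, ...) {
  focal <- as_circular_seq(focal, "focal")
  if (!length(comparators)) stop("at least one comparator is required")
  if (inherits(comparators, "CircularSeq")) comparators <- list(comparators)
  L <- focal$length
  cov <- IRanges::IRanges()
  for (cmp in comparators) {
    m <- find_local_matches(focal, cmp, min_len = cover_min_len,
                            min_identity = cover_min_identity,
                            self = FALSE, ...)
    cov <- IRanges::reduce(c(cov, covered_ranges(m, L)))
  }
  unc <- IRanges::setdiff(IRanges::IRanges(1L, L), cov)
  df <- data.frame(start = IRanges::start(unc), end = IRanges::end(unc))
  wraps <- rep(FALSE, nrow(df))
  if (focal$circular && nrow(df) >= 2L &&
      df$start[1] == 1L && df$end[nrow(df)] == L) {
    # merge the two runs flanking the origin into one wrapping region
    df$end[nrow(df)] <- df$end[1]
    wraps[nrow(df)] <- TRUE
    df <- df[-1L, , drop = FALSE]
    wraps <- wraps[-1L]
  }
  len <- ifelse(wraps, L - df$start + 1L + df$end, df$end - df$start + 1L)
  keep <- len >= min_unique_len
  df <- df[keep, , drop = FALSE]; len <- len[keep]; wraps <- wraps[keep]
  out <- data.frame(label = if (nrow(df)) paste0("U", seq_len(nrow(df)))
                            else character(0),
                    start = df$start, end = df$end, length = len,
                    wraps = wraps, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "fraction_unique") <- sum(len) / L
  attr(out, "L") <- L
  out
}

#' Detect chloroplast-derived segments in a mitochondrial genome
#'
#' High-identity local matches of the mitochondrial genome against the
#' plastid genome, filtered, de-overlapped on the mitochondrial side and
#' labelled H1... by length, descending.
#'
#' @param mt mitochondrial \code{\link{circular_seq}}.
#' @param cp chloroplast \code{\link{circular_seq}}.
#' @param min_identity minimum identity (default 0.95).
#' @param min_len minimum segment length in bp (default 100).
#' @param ... further aligner parameters.
#' @return data.frame (label, start, end, cp_start, cp_end, strand,
#'   identity, length) with attributes \code{fraction} and \code{L}.
#' @export
find_cp_segments <- function(mt, cp, min_identity = 0.95, min_len = 100L, ...) {
  mt <- as_circular_seq(mt, "mt"); cp <- as_circular_seq(cp, "cp")
  m <- as.data.frame(find_local_matches(mt, cp, min_len = min_len,
                                        min_identity = min_identity,
                                        self = FALSE, ...))
  if (nrow(m)) {
    m$len <- ifelse(m$q_end >= m$q_start, m$q_end - m$q_start + 1L,
                    mt$length - m$q_start + 1L + m$q_end)
    m <- m[order(-m$len), , drop = FALSE]
    # drop segments mostly contained in an already-kept one (mt side)
    keep <- logical(nrow(m))
    for (i in seq_len(nrow(m))) {
      ok <- TRUE
      for (j in which(keep)) {
        ov <- min(m$q_end[i], m$q_end[j]) - max(m$q_start[i], m$q_start[j]) + 1L
        if (ov > 0.5 * m$len[i]) { ok <- FALSE; break }
      }
      keep[i] <- ok
    }
    m <- m[keep, , drop = FALSE]
  }
  out <- data.frame(label = if (nrow(m)) paste0("H", seq_len(nrow(m)))
                            else character(0),
                    start = m$q_start, end = m$q_end,
                    cp_start = m$t_start, cp_end = m$t_end,
                    strand = m$strand, identity = m$identity,
                    length = if (nrow(m)) m$len else integer(0),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "fraction") <- sum(out$length) / mt$length
  attr(out, "L") <- mt$length
  out
}

#' Classify ORFs as shared, partial or unique across comparators
#'
#' An ORF is \code{shared} when some comparator carries a near-full-length
#' copy at \code{shared_min_identity}; \code{partial} when at least
#' \code{partial_min_cover} of its length is matched somewhere but no
#' full-length high-identity copy exists; \code{unique} otherwise.
#' Unique ORFs are intersected with the unique regions (if supplied) to
#' flag candidate exogenous introgressions.
#'
#' @param orfs data.frame from \code{\link{find_orfs}} (needs
#'   \code{orf_id, start, end, seq}).
#' @param comparators list of comparator genomes.
#' @param shared_min_identity identity for a shared call (default 0.99).
#' @param partial_min_cover fraction of ORF length for a partial call
#'   (default 0.30).
#' @param full_cover fraction of ORF length counting as full length.
#' @param unique_regions optional data.frame from
#'   \code{\link{call_unique_regions}}.
#' @param ... further aligner parameters.
#' @return the ORF table with \code{sharedness} and
#'   \code{in_unique_region} columns added.
#' @export
classify_orf_sharedness <- function(orfs, comparators,
                                    shared_min_identity = 0.99,
                                    partial_min_cover = 0.30,
                                    full_cover = 0.90,
                                    unique_regions = NULL, ...) {
  if (inherits(comparators, "CircularSeq")) comparators <- list(comparators)
  n <- nrow(orfs)
  sharedness <- character(n)
  for (i in seq_len(n)) {
    oseq <- circular_seq(orfs$orf_id[i], orfs$seq[i], circular = FALSE)
    olen <- nchar(orfs$seq[i])
    shared <- FALSE; covmax <- 0
    for (cmp in comparators) {
      m <- as.data.frame(find_local_matches(
        oseq, cmp, min_len = max(30L, min(olen, 50L)),
        min_identity = 0.85, self = FALSE, ...))
      if (!nrow(m)) next
      hi <- m[m$identity >= shared_min_identity, , drop = FALSE]
      if (nrow(hi) &&
          any((hi$q_end - hi$q_start + 1L) >= full_cover * olen)) shared <- TRUE
      covmax <- max(covmax, union_span(m$q_start, m$q_end, olen) / olen)
      if (shared) break
    }
    sharedness[i] <- if (shared) "shared"
                     else if (covmax >= partial_min_cover) "partial"
                     else "unique"
  }
  orfs$sharedness <- sharedness
  inu <- rep(FALSE, n)
  if (!is.null(unique_regions) && nrow(unique_regions)) {
    for (i in seq_len(n)) {
      ov <- pmin(orfs$end[i], unique_regions$end) -
            pmax(orfs$start[i], unique_regions$start) + 1L
      inu[i] <- any(ov > 0L)
    }
  }
  orfs$in_unique_region <- inu
  orfs
}
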