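# Intramolecular homologous recombination across repeat pairs: a direct
# repeat pair resolves the master circle into two subgenomic circles
# whose sizes sum to L (each keeping one fused repeat copy); an inverted
# pair yields an equal-length isomer with the inter-copy arc reversed.
# Short repeats flanking syntenic-junction breakpoints are scored as
# candidate mediators of observed rearrangements.

#' Predict the two subgenomic circles generated by a direct repeat pair
#'
#' Sizes are measured start-of-copy to start-of-copy around the master
#' circle, so each subcircle contains exactly one full repeat copy and
#' the two sizes sum to the master length.
#'
#' @param master a circular \code{\link{circular_seq}}.
#' @param pair one repeat pair (single-row data.frame or list with
#'   \code{kind, start1, end1, start2, end2}).
#' @param emit_seq also return the subcircle sequences (default TRUE).
#' @return list of two \code{SubgenomicCircle} objects, each with
#'   \code{size}, \code{arc} (the master-circle interval it derives
#'   from), \code{carries_repeat_copy} and optionally \code{seq}.
#' @export
predict_subgenomic_circles <- function(master, pair, emit_seq = TRUE) {
  master <- as_circular_seq(master, "master")
  if (!master$circular) stop("subgenomic circles require a circular master")
  p <- as.list(pair)
  if (!identical(as.character(p$kind), "direct")) {
    stop("pair is not a direct repeat; see predict_inverted_isomer")
  }
  if (!(p$end1 < p$start2 || p$end2 < p$start1)) stop("repeat copies overlap")
  L <- master$length
  s1 <- as.integer(p$start1); s2 <- as.integer(p$start2)
  d <- (s2 - s1) %% L
  mk <- function(from, to, size, copy) {
    circ <- list(size = size,
                 arc = interval(from, if (to %% L == 0L) L else to %% L),
                 carries_repeat_copy = copy)
    if (emit_seq) {
      circ$seq <- circular_seq(paste0(master$id, "_sub", copy),
                               extract_interval(master, circ$arc))
    }
    structure(circ, class = "SubgenomicCircle")
  }
  # circle 1: arc [s1, s2-1] (carries copy 1); circle 2: the complement
  c1 <- mk(s1, s2 - 1L, d, 1L)
  c2 <- mk(s2, s1 - 1L, L - d, 2L)
  list(c1, c2)
}

#' @export
print.SubgenomicCircle <- function(x, ...) {
  cat(sprintf("<SubgenomicCircle> %d bp (copy %d; arc %d..%d)\n",
              x$size, x$carries_repeat_copy, x$arc$start, x$arc$end))
  invisible(x)
}

#' Predict the isomeric form generated by an inverted repeat pair
#'
#' Returns an equal-length circle with the arc strictly between the two
#' repeat copies reverse-complemented; applying the operation twice
#' restores the original molecule.
#'
#' @param master a circular \code{\link{circular_seq}}.
#' @param pair one inverted repeat pair.
#' @export
predict_inverted_isomer <- function(master, pair) {
  master <- as_circular_seq(master, "master")
  p <- as.list(pair)
  if (!identical(as.character(p$kind), "inverted")) {
    stop("pair is not an inverted repeat; see predict_subgenomic_circles")
  }
  e1 <- as.integer(p$end1); s2 <- as.integer(p$start2)
  L <- master$length
  if (s2 - e1 <= 1L) return(master)  # zero-length inter-copy arc
  mid <- revcomp(substr(master$seq, e1 + 1L, s2 - 1L))
  circular_seq(paste0(master$id, "_isomer"),
               paste0(substr(master$seq, 1L, e1), mid,
                      substr(master$seq, s2, L)),
               circular = master$circular)
}

#' Canonical rotation of a circular sequence
#'
#' The lexicographically minimal rotation (two-pointer duel algorithm,
#' linear time), used for rotation-normalised equality testing of
#' circles.
#'
#' @param s nucleotide string.
#' @return the rotated string.
#' @export
canonical_rotation <- function(s) {
  n <- nchar(s)
  if (n <= 1L) return(s)
  x <- utf8ToInt(paste0(s, s))
  i <- 1L; j <- 2L; k <- 0L
  while (i <= n && j <= n && k < n) {
    a <- x[i + k]; b <- x[j + k]
    if (a == b) {
      k <- k + 1L
    } else if (a > b) {
      i <- i + k + 1L; k <- 0L; if (i == j) i <- i + 1L
    } else {
      j <- j + k + 1L; k <- 0L; if (i == j) j <- j + 1L
    }
  }
  start <- min(i, j)
  substr(paste0(s, s), start, start + n - 1L)
}

#' Rotation-normalised equality of two circular sequences
#'
#' @param a,b nucleotide strings or CircularSeq objects.
#' @export
rotation_identical <- function(a, b) {
  a <- if (inherits(a, "CircularSeq")) a$seq else a
  b <- if (inherits(b, "CircularSeq")) b$seq else b
  nchar(a) == nchar(b) && grepl(b, paste0(a, a), fixed = TRUE)
}

# circular distance from a point to the nearest end of an interval
circ_point_dist <- function(p, s, e, L) {
  if (s <= e) {
    if (p >= s && p <= e) return(0L)
  } else if (p >= s || p <= e) return(0L)
  d1 <- min(abs(p - s), L - abs(p - s))
  d2 <- min(abs(p - e), L - abs(p - e))
  min(d1, d2)
}

#' Explain syntenic-junction rearrangements by flanking repeats
#'
#' For each adjacency of syntenic regions in genome B whose A-side images
#' are not adjacent (a rearrangement junction), every repeat pair of
#' genome A is tested for copies lying within \code{flank_window} of both
#' A-side breakpoints.  All candidates within 10x the window are emitted
#' with their offsets; \code{plausible} flags those with both offsets
#' within the window.  A junction with no candidate at all is still
#' reported (offsets NA, not plausible).
#'
#' @param m a \code{SyntenyMap} between genomes A and B.
#' @param repeats data.frame of repeat pairs on genome A.
#' @param flank_window maximum breakpoint-to-copy distance for a
#'   plausible mediator (default 500 bp).
#' @param adjacency_tol A-side gap below which regions count as adjacent.
#' @return data.frame with junction id, flanking region labels, repeat
#'   pair index and coordinates, offsets and the plausible flag.
#' @export
explain_junctions_by_repeats <- function(m, repeats, flank_window = 500L,
                                         adjacency_tol = 200L) {
  r <- m$regions
  empty <- data.frame(junction = character(0), left = character(0),
                      right = character(0), repeat_id = integer(0),
                      offset1 = integer(0), offset2 = integer(0),
                      plausible = logical(0), stringsAsFactors = FALSE)
  if (nrow(r) < 2L) return(empty)
  L <- m$L_a
  bo <- order(pmin(r$b_start, r$b_end))
  out <- list()
  for (z in seq_len(length(bo))) {
    i <- bo[z]; j <- bo[if (z == length(bo)) 1L else z + 1L]
    if (i == j) next
    # A-side breakpoints facing this B-adjacency
    bp_i <- if (r$orientation[i] == "same") r$a_end[i] else r$a_start[i]
    bp_j <- if (r$orientation[j] == "same") r$a_start[j] else r$a_end[j]
    gap_a <- min(abs(bp_j - bp_i), L - abs(bp_j - bp_i))
    if (gap_a <= adjacency_tol) next  # co-linear in A too: not a junction
    jid <- paste0(r$label[i], "|", r$label[j])
    found <- FALSE
    if (nrow(repeats)) {
      for (k in seq_len(nrow(repeats))) {
        o1a <- circ_point_dist(bp_i, repeats$start1[k], repeats$end1[k], L)
        o2a <- circ_point_dist(bp_j, repeats$start2[k], repeats$end2[k], L)
        o1b <- circ_point_dist(bp_i, repeats$start2[k], repeats$end2[k], L)
        o2b <- circ_point_dist(bp_j, repeats$start1[k], repeats$end1[k], L)
        if (max(o1a, o2a) <= max(o1b, o2b)) { o1 <- o1a; o2 <- o2a }
        else { o1 <- o1b; o2 <- o2b }
        if (max(o1, o2) <= 10L * flank_window) {
          found <- TRUE
          out[[length(out) + 1L]] <- data.frame(
            junction = jid, left = r$label[i], right = r$label[j],
            repeat_id = k, offset1 = o1, offset2 = o2,
            plausible = max(o1, o2) <= flank_window,
            stringsAsFactors = FALSE)
        }
      }
    }
    if (!found) {
      out[[length(out) + 1L]] <- data.frame(
        junction = jid, left = r$label[i], right = r$label[j],
        repeat_id = NA_integer_, offset1 = NA_integer_,
        offset2 = NA_integer_, plausible = FALSE, stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
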