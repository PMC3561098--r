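# Core data model: circular sequences, 1-based inclusive intervals with
# wraparound, gene models, FASTA/GFF3/TSV/BED I/O.

#' Construct a circular (or linear) nucleotide sequence
#'
#' @param id sequence label.
#' @param seq nucleotide string over \code{A,C,G,T,N} (lower case accepted).
#' @param circular logical; is the molecule circular?
#' @return an object of class \code{CircularSeq} with fields \code{id},
#'   \code{seq}, \code{circular}, \code{length}.
#' @export
circular_seq <- function(id, seq, circular = TRUE) {
  stopifnot(is.character(seq), length(seq) == 1L)
  seq <- toupper(seq)
  if (nchar(seq) == 0L) stop("empty sequence for record '", id, "'")
  bad <- regexpr("[^ACGTN]", seq)
  if (bad > 0L) {
    stop("non-nucleotide character '", substr(seq, bad, bad),
         "' in record '", id, "' at position ", bad)
  }
  structure(list(id = as.character(id), seq = seq,
                 circular = isTRUE(circular), length = nchar(seq)),
            class = "CircularSeq")
}

#' @export
print.CircularSeq <- function(x, ...) {
  cat(sprintf("<CircularSeq> %s: %d bp, %s, GC %.2f%%\n", x$id, x$length,
              if (x$circular) "circular" else "linear", 100 * gc_content(x)))
  invisible(x)
}

as_circular_seq <- function(x, id = "seq", circular = TRUE) {
  if (inherits(x, "CircularSeq")) return(x)
  circular_seq(id, x, circular)
}

#' 1-based inclusive interval, optionally wrapping the origin
#'
#' An interval with \code{start > end} wraps the origin of a circular
#' sequence.  Coordinates are 1-based and inclusive throughout the package.
#'
#' @param start,end 1-based inclusive endpoints.
#' @param strand \code{"+"} or \code{"-"}.
#' @return an object of class \code{Interval}.
#' @export
interval <- function(start, end, strand = "+") {
  stopifnot(start >= 1, end >= 1, strand %in% c("+", "-"))
  structure(list(start = as.integer(start), end = as.integer(end),
                 strand = strand, wraps = start > end),
            class = "Interval")
}

#' Number of bases covered by an interval on a sequence of length L
#'
#' @param iv an \code{\link{interval}}.
#' @param L sequence length (needed for wrapping intervals).
#' @export
iv_span <- function(iv, L = NULL) {
  if (iv$wraps) {
    if (is.null(L)) stop("L is required for a wrapping interval")
    L - iv$start + 1L + iv$end
  } else {
    iv$end - iv$start + 1L
  }
}

# Split an interval into non-wrapping (start, end) pieces for union algebra.
iv_pieces <- function(start, end, L) {
  if (start <= end) {
    cbind(start = start, end = end)
  } else {
    rbind(cbind(start = start, end = L), cbind(start = 1L, end = end))
  }
}

#' Gene model: one or more exon intervals plus metadata
#'
#' @param gene_id gene identifier.
#' @param intervals data.frame with columns \code{start}, \code{end},
#'   \code{strand} (one row per exon, in transcription order).
#' @param type one of \code{"protein"}, \code{"tRNA"}, \code{"rRNA"},
#'   \code{"orf"}.
#' @param product free-text product description.
#' @export
gene_model <- function(gene_id, intervals, type = "protein", product = "") {
  stopifnot(is.data.frame(intervals), nrow(intervals) >= 1L,
            all(c("start", "end", "strand") %in% names(intervals)))
  type <- match.arg(type, c("protein", "tRNA", "rRNA", "orf"))
  structure(list(gene_id = gene_id, intervals = intervals, type = type,
                 product = product), class = "GeneModel")
}

#' Read genome FASTA into a list of CircularSeq
#'
#' Sequences are uppercased and validated against the \code{A,C,G,T,N}
#' alphabet; a violation is reported with the record name and offset.
#' Circularity defaults to \code{circular} but a header containing the
#' token \code{linear} (or \code{circular=false}) marks a record linear.
#'
#' @param path FASTA file.
#' @param circular default circularity flag.
#' @return named list of \code{\link{circular_seq}} objects.
#' @export
read_genome_fasta <- function(path, circular = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path)
  ss <- Biostrings::readBStringSet(path)
  if (length(ss) == 0L) stop("no FASTA records in ", path)
  out <- vector("list", length(ss))
  for (i in seq_along(ss)) {
    hdr <- names(ss)[i]
    id <- strsplit(hdr, "[ \t]")[[1]][1]
    circ <- circular
    if (grepl("\\blinear\\b", hdr, ignore.case = TRUE) ||
        grepl("circular=false", hdr, ignore.case = TRUE)) circ <- FALSE
    if (grepl("circular=true", hdr, ignore.case = TRUE)) circ <- TRUE
    out[[i]] <- circular_seq(id, as.character(ss[[i]]), circ)
  }
  names(out) <- vapply(out, `[[`, "", "id")
  out
}

#' Write CircularSeq objects to FASTA
#'
#' @param seqs a CircularSeq or list of them.
#' @param path output file.
#' @export
write_genome_fasta <- function(seqs, path) {
  if (inherits(seqs, "CircularSeq")) seqs <- list(seqs)
  ss <- Biostrings::DNAStringSet(vapply(seqs, `[[`, "", "seq"))
  names(ss) <- vapply(seqs, `[[`, "", "id")
  Biostrings::writeXStringSet(ss, path, width = 70L)
  invisible(path)
}

#' Reverse complement of a nucleotide string
#' @param s nucleotide string.
#' @export
revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

#' Extract the bases covered by an interval
#'
#' Wrapping intervals are only valid on circular sequences; minus-strand
#' intervals return the reverse complement.
#'
#' @param seq a \code{\link{circular_seq}}.
#' @param iv an \code{\link{interval}}.
#' @export
extract_interval <- function(seq, iv) {
  seq <- as_circular_seq(seq)
  L <- seq$length
  if (iv$start > L || iv$end > L) stop("interval exceeds sequence length ", L)
  if (iv$wraps && !seq$circular) {
    stop("wrapping interval on a linear sequence '", seq$id, "'")
  }
  s <- if (iv$wraps) {
    paste0(substr(seq$seq, iv$start, L), substr(seq$seq, 1L, iv$end))
  } else {
    substr(seq$seq, iv$start, iv$end)
  }
  if (iv$strand == "-") revcomp(s) else s
}

#' G+C fraction of a sequence, ignoring N
#'
#' @param seq a CircularSeq or nucleotide string.
#' @return fraction in [0, 1].
#' @export
gc_content <- function(seq) {
  s <- if (inherits(seq, "CircularSeq")) seq$seq else toupper(seq)
  f <- Biostrings::letterFrequency(Biostrings::BString(s),
                                   c("A", "C", "G", "T"))
  tot <- sum(f)
  if (tot == 0L) stop("GC content undefined: no unambiguous bases")
  unname((f[["G"]] + f[["C"]]) / tot)
}

#' Read gene annotations from GFF3 or a 4/5-column TSV
#'
#' The TSV dialect is \code{gene_id, start, end, strand[, type]} with a
#' header line.  GFF3 parsing goes through \pkg{rtracklayer}; \code{gene}
#' and \code{CDS} features are retained.
#'
#' @param path annotation file.
#' @param format \code{"auto"}, \code{"gff3"} or \code{"tsv"}.
#' @return data.frame with columns \code{gene_id, start, end, strand, type}.
#' @export
read_gene_annotations <- function(path, format = c("auto", "gff3", "tsv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.gff3?$", path, ignore.case = TRUE)) "gff3" else "tsv"
  }
  if (format == "gff3") {
    gr <- rtracklayer::import(path, format = "gff3")
    gr <- gr[as.character(gr$type) %in% c("gene", "CDS", "ORF")]
    ids <- if (!is.null(gr$ID)) as.character(gr$ID) else as.character(gr$Name)
    df <- data.frame(gene_id = ids,
                     start = BiocGenerics::start(gr),
                     end = BiocGenerics::end(gr),
                     strand = as.character(BiocGenerics::strand(gr)),
                     type = as.character(gr$type),
                     stringsAsFactors = FALSE)
    df$strand[!df$strand %in% c("+", "-")] <- "+"
    df
  } else {
    df <- read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
    stopifnot(all(c("gene_id", "start", "end", "strand") %in% names(df)))
    if (is.null(df$type)) df$type <- "gene"
    df
  }
}

#' Write features as GFF3
#'
#' @param df data.frame with \code{gene_id, start, end, strand} and
#'   optionally \code{type}.
#' @param path output file.
#' @param seqname sequence name for column 1.
#' @export
write_gff3 <- function(df, path, seqname = "genome") {
  gr <- GenomicRanges::GRanges(
    seqnames = seqname,
    ranges = IRanges::IRanges(start = df$start, end = df$end),
    strand = ifelse(df$strand %in% c("+", "-"), df$strand, "*"))
  gr$ID <- df$gene_id
  gr$type <- if (is.null(df$type)) "gene" else df$type
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Export intervals as BED (0-based half-open)
#'
#' The package is 1-based inclusive everywhere; the conversion happens
#' only at this boundary, via \pkg{rtracklayer}.
#'
#' @param df data.frame with \code{start, end} and optionally
#'   \code{name, strand}.
#' @param path output .bed file.
#' @param seqname chromosome/sequence name.
#' @export
export_bed <- function(df, path, seqname = "genome") {
  gr <- GenomicRanges::GRanges(
    seqnames = seqname,
    ranges = IRanges::IRanges(start = df$start, end = df$end),
    strand = if (!is.null(df$strand)) {
      ifelse(df$strand %in% c("+", "-"), df$strand, "*")
    } else "*")
  if (!is.null(df$name)) names(gr) <- df$name
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}

# Union length of a set of (possibly wrapping) intervals on a circle of
# length L, each position counted once.  Delegates to IRanges::reduce.
union_span <- function(starts, ends, L) {
  if (length(starts) == 0L) return(0L)
  pieces <- do.call(rbind, Map(iv_pieces, starts, ends, MoreArgs = list(L = L)))
  ir <- IRanges::reduce(IRanges::IRanges(start = pieces[, "start"],
                                         end = pmin(pieces[, "end"], L)))
  sum(IRanges::width(ir))
}
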