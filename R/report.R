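# Aggregate run report: one summary block per genome in the shape of a
# mitotype-composition table (size, GC%, gene/ORF counts, unique-region
# %, cp-derived %, large-repeat lengths, short-repeat %).  Every number
# in the report is recomputable from the stage outputs; the report does
# no arithmetic of its own beyond percent formatting.

fmt_pct <- function(x) sprintf("%.2f", round(100 * x, 2))

#' Build an aggregate composition report from stage outputs
#'
#' @param stages named list, one element per genome; each element is a
#'   list that may contain \code{genome} (CircularSeq, required),
#'   \code{genes} (annotation data.frame), \code{orfs}
#'   (\code{\link{find_orfs}} table), \code{unique}
#'   (\code{\link{call_unique_regions}} table), \code{cp}
#'   (\code{\link{find_cp_segments}} table), \code{repeats}
#'   (\code{\link{repeat_set}} object), \code{synteny}
#'   (\code{SyntenyMap}).
#' @return object of class \code{mt_report}: a feature-by-genome
#'   character data.frame with a \code{values} attribute holding the
#'   unformatted numbers.
#' @export
build_report <- function(stages) {
  if (!length(stages)) stop("no stage outputs supplied")
  if (is.null(names(stages)) || any(names(stages) == "")) {
    stop("stages must be a named list (one name per genome)")
  }
  feats <- c("Genome size (bp)", "GC%", "Genes", "ORFs",
             "Unique region (%)", "cp-derived sequences (%)",
             "Large repeat (bp)", "Short repeat (%)",
             "Synteny coverage (%)")
  out <- data.frame(row.names = feats)
  vals <- list()
  for (nm in names(stages)) {
    st <- stages[[nm]]
    if (is.null(st$genome)) stop("stage '", nm, "' has no genome")
    g <- st$genome
    v <- list(size = g$length, gc = gc_content(g))
    col <- c(format(g$length), fmt_pct(v$gc))
    col <- c(col, if (!is.null(st$genes)) format(nrow(st$genes)) else "-")
    col <- c(col, if (!is.null(st$orfs)) format(nrow(st$orfs)) else "-")
    if (!is.null(st$unique)) {
      v$unique_fraction <- attr(st$unique, "fraction_unique")
      col <- c(col, fmt_pct(v$unique_fraction))
    } else col <- c(col, "-")
    if (!is.null(st$cp)) {
      v$cp_fraction <- attr(st$cp, "fraction")
      col <- c(col, fmt_pct(v$cp_fraction))
    } else col <- c(col, "-")
    if (!is.null(st$repeats)) {
      lr <- st$repeats$large
      v$large_repeats <- lr$rep_len
      v$short_fraction <- st$repeats$short_fraction
      col <- c(col, if (nrow(lr)) paste(lr$rep_len, collapse = ",") else "-",
               fmt_pct(v$short_fraction))
    } else col <- c(col, "-", "-")
    if (!is.null(st$synteny)) {
      v$coverage_a <- st$synteny$coverage_a
      col <- c(col, fmt_pct(v$coverage_a))
    } else col <- c(col, "-")
    out[[nm]] <- col
    vals[[nm]] <- v
  }
  attr(out, "values") <- vals
  class(out) <- c("mt_report", "data.frame")
  out
}

#' @export
print.mt_report <- function(x, ...) {
  cat("Mitotype composition report\n")
  print.data.frame(x)
  invisible(x)
}

#' Write a data.frame as TSV with one commented header line
#'
#' @param df data.frame.
#' @param path output file.
#' @export
write_stage_tsv <- function(df, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", paste(names(df), collapse = "\t")), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Run the full comparative pipeline on a focal genome
#'
#' Convenience driver: synteny against the first comparator, repeat
#' catalogue, subgenomic-circle prediction from the longest direct large
#' repeat, unique regions against all comparators, chloroplast-derived
#' segments, ORFs with sharedness, and the aggregate report.
#'
#' @param focal focal \code{\link{circular_seq}}.
#' @param comparators list of comparator genomes.
#' @param cp chloroplast genome, or NULL to skip MTPT detection.
#' @param genes optional gene annotation data.frame.
#' @param min_orf_len minimum ORF length (default 300).
#' @param ... forwarded to the stage functions where applicable.
#' @return list with the stage outputs and \code{report}.
#' @export
run_pipeline <- function(focal, comparators, cp = NULL, genes = NULL,
                         min_orf_len = 300L, ...) {
  focal <- as_circular_seq(focal, "focal")
  if (inherits(comparators, "CircularSeq")) comparators <- list(comparators)
  syn <- detect_syntenic_regions(focal, comparators[[1]])
  reps <- repeat_set(focal)
  circles <- NULL
  lr <- reps$large[reps$large$kind == "direct", , drop = FALSE]
  if (nrow(lr)) circles <- predict_subgenomic_circles(focal, lr[1, ],
                                                      emit_seq = FALSE)
  uniq <- call_unique_regions(focal, comparators)
  cpseg <- if (!is.null(cp)) find_cp_segments(focal, cp) else NULL
  orfs <- find_orfs(focal, min_orf_len = min_orf_len)
  if (nrow(orfs)) {
    orfs <- classify_orf_sharedness(orfs, comparators,
                                    unique_regions = uniq)
  }
  stages <- list(focal = list(genome = focal, genes = genes, orfs = orfs,
                              unique = uniq, cp = cpseg, repeats = reps,
                              synteny = syn))
  list(synteny = syn, repeats = reps, circles = circles, unique = uniq,
       cp_segments = cpseg, orfs = orfs, report = build_report(stages))
}
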