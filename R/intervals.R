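# Genomic intervals: 0-based half-open (BED convention) throughout the
# package. Conversion to IRanges (1-based closed) happens only inside these
# helpers; public data frames always carry BED coordinates.

validate_intervals <- function(x, what = "interval") {
  stopifnot(is.data.frame(x), all(c("chrom", "start", "end") %in% names(x)))
  bad <- which(!is.na(x$start) & !is.na(x$end) & x$start >= x$end)
  if (length(bad))
    stop(sprintf("malformed %s (start >= end) at record(s): %s",
                 what, paste(utils::head(bad, 5L), collapse = ", ")))
  if (any(!nzchar(as.character(x$chrom))))
    stop(sprintf("malformed %s: empty chromosome name", what))
  invisible(x)
}

as_granges0 <- function(x) {
  GenomicRanges::GRanges(
    seqnames = as.character(x$chrom),
    ranges = IRanges::IRanges(start = x$start + 1L, end = x$end)
  )
}

granges_to_bed <- function(gr) {
  data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    stringsAsFactors = FALSE
  )
}

#' Merge genomic intervals that lie within a gap of each other
#'
#' Intervals on the same chromosome separated by at most `gap` base pairs
#' (end-to-start distance; overlap counts as gap <= 0) are merged
#' transitively. This is the anchor-merging step used before building the
#' interaction network, with the conventional 2 kbp gap.
#'
#' @param intervals Data frame with columns `chrom`, `start`, `end`
#'   (0-based half-open).
#' @param gap Maximum separation in bp that still forces a merge
#'   (default 2000).
#' @return Data frame of merged intervals, sorted by chromosome and start;
#'   any two output intervals on one chromosome are separated by more than
#'   `gap` bp.
#' @examples
#' merge_intervals(data.frame(chrom = "chr1", start = c(0, 1500),
#'                            end = c(100, 1600)))
#' @export
merge_intervals <- function(intervals, gap = 2000L) {
  stopifnot(gap >= 0)
  validate_intervals(intervals)
  if (nrow(intervals) == 0L) return(intervals[, c("chrom", "start", "end")])
  gr <- as_granges0(intervals)
  # IRanges gapwidth equals the BED end-to-start distance; min.gapwidth = gap+1
  # merges whenever that distance is <= gap
  merged <- GenomicRanges::reduce(GenomicRanges::sort(gr),
                                  min.gapwidth = gap + 1L)
  out <- granges_to_bed(merged)
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read chromatin interaction anchor pairs
#'
#' Tab-separated, BEDPE-compatible: columns
#' `chrom1 start1 end1 chrom2 start2 end2 [score ...]`; extra columns are
#' ignored and `#` comment lines skipped.
#'
#' @param path Path to the interaction file.
#' @return Data frame with columns `chrom1,start1,end1,chrom2,start2,end2`
#'   and `score` when a numeric 7th column is present.
#' @export
read_interactions <- function(path) {
  x <- utils::read.table(path, sep = "\t", header = FALSE, comment.char = "#",
                         stringsAsFactors = FALSE)
  if (ncol(x) < 6L)
    stop("interaction file must have at least 6 tab-separated columns")
  out <- data.frame(
    chrom1 = as.character(x[[1]]), start1 = as.integer(x[[2]]),
    end1 = as.integer(x[[3]]),
    chrom2 = as.character(x[[4]]), start2 = as.integer(x[[5]]),
    end2 = as.integer(x[[6]]), stringsAsFactors = FALSE
  )
  if (ncol(x) >= 7L && is.numeric(x[[7]])) out$score <- x[[7]]
  validate_intervals(data.frame(chrom = out$chrom1, start = out$start1,
                                end = out$end1), "anchor 1")
  validate_intervals(data.frame(chrom = out$chrom2, start = out$start2,
                                end = out$end2), "anchor 2")
  out
}

#' Read a BED3+ peak file
#'
#' Accepts plain BED and ENCODE narrowPeak. Column 4 is kept as `name` and
#' column 7 (narrowPeak signalValue) as `score` when present; further
#' columns are ignored.
#'
#' @param path Path to the BED file.
#' @return Data frame with columns `chrom`, `start`, `end`, and optionally
#'   `name` and `score`.
#' @export
read_peaks <- function(path) {
  x <- utils::read.table(path, sep = "\t", header = FALSE, comment.char = "#",
                         stringsAsFactors = FALSE)
  if (ncol(x) < 3L) stop("BED file must have at least 3 columns")
  out <- data.frame(chrom = as.character(x[[1]]), start = as.integer(x[[2]]),
                    end = as.integer(x[[3]]), stringsAsFactors = FALSE)
  if (ncol(x) >= 4L) out$name <- as.character(x[[4]])
  if (ncol(x) >= 7L && is.numeric(x[[7]])) out$score <- x[[7]]
  validate_intervals(out, basename(path))
  out
}

#' @rdname read_peaks
#' @export
read_bed <- read_peaks
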