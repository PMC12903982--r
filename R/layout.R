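# Genome layout and interval primitives.
#
# Every coordinate inside the package is 0-based, half-open [start, end).
# Conversion to and from 1-based conventions (GFF3, cytosine reports,
# GRanges) happens only at the file/container boundary.

#' Define a genome layout
#'
#' A layout is the coordinate frame all tracks share: chromosome names and
#' lengths. All accessions are assumed to be expressed on one shared
#' reference frame.
#'
#' @param chrom Character vector of unique chromosome names.
#' @param length Integer vector of chromosome lengths in bp (> 0).
#' @return A `data.frame` with columns `chrom`, `length` and class
#'   `genome_layout`.
#' @export
genome_layout <- function(chrom, length) {
  chrom <- as.character(chrom)
  length <- as.numeric(length)
  if (anyDuplicated(chrom)) stop("chromosome names must be unique")
  if (length(chrom) != base::length(length)) {
    stop("chrom and length must have equal length")
  }
  if (any(!is.finite(length)) || any(length <= 0) || any(length != floor(length))) {
    stop("chromosome lengths must be positive integers")
  }
  structure(data.frame(chrom = chrom, length = length,
                       stringsAsFactors = FALSE),
            class = c("genome_layout", "data.frame"))
}

#' Total genome size of a layout
#' @param layout A [genome_layout()].
#' @return Total length in bp.
#' @export
genome_size <- function(layout) sum(layout$length)

chrom_length <- function(layout, chrom) {
  i <- match(chrom, layout$chrom)
  if (anyNA(i)) stop("unknown chromosome: ", paste(chrom[is.na(i)], collapse = ", "))
  layout$length[i]
}

#' Construct a set of genomic intervals
#'
#' Intervals are 0-based half-open. When a layout is supplied every interval
#' is validated against it.
#'
#' @param chrom Character vector.
#' @param start,end Numeric vectors, 0-based half-open; `0 <= start < end`.
#' @param layout Optional [genome_layout()] for bounds checking.
#' @param ... Additional columns recycled to the interval count.
#' @return A `data.frame` with columns `chrom`, `start`, `end` plus extras.
#' @export
genomic_intervals <- function(chrom, start, end, layout = NULL, ...) {
  x <- data.frame(chrom = as.character(chrom), start = as.numeric(start),
                  end = as.numeric(end), ..., stringsAsFactors = FALSE)
  validate_intervals(x, layout)
  x
}

validate_intervals <- function(x, layout = NULL, what = "interval") {
  stopifnot(all(c("chrom", "start", "end") %in% names(x)))
  if (nrow(x) == 0) return(invisible(x))
  bad <- which(!(x$start >= 0 & x$start < x$end))
  if (length(bad)) {
    stop(sprintf("invalid %s (start >= end or start < 0) at row %d: %s:%s-%s",
                 what, bad[1], x$chrom[bad[1]], x$start[bad[1]], x$end[bad[1]]))
  }
  if (!is.null(layout)) {
    i <- match(x$chrom, layout$chrom)
    if (anyNA(i)) {
      stop("unknown chromosome in ", what, ": ",
           paste(unique(x$chrom[is.na(i)]), collapse = ", "))
    }
    over <- which(x$end > layout$length[i])
    if (length(over)) {
      stop(sprintf("%s extends past chromosome end at row %d (%s:%s-%s)",
                   what, over[1], x$chrom[over[1]], x$start[over[1]],
                   x$end[over[1]]))
    }
  }
  invisible(x)
}

# GRanges bridge: GRanges is 1-based closed, so shift start by +1.
as_granges <- function(x) {
  GenomicRanges::GRanges(
    seqnames = x$chrom,
    ranges = IRanges::IRanges(start = x$start + 1L, end = x$end)
  )
}

from_granges <- function(gr) {
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1,
             end = GenomicRanges::end(gr),
             stringsAsFactors = FALSE)
}

#' Tile a genome into windows
#'
#' Tiles each chromosome left to right with windows of `size` bp advancing
#' by `step` bp; the terminal partial window is retained. With the default
#' `step = size` the result is the non-overlapping tiling used for 1-kb DMR
#' windows, 100-bp AMR windows and 500-kb chromosome profiles.
#'
#' @param layout A [genome_layout()].
#' @param size Window size in bp (> 0).
#' @param step Step in bp (> 0); defaults to `size`.
#' @return Interval `data.frame` with a `window_id` column.
#' @export
tile_windows <- function(layout, size, step = size) {
  if (!inherits(layout, "genome_layout")) stop("layout must be a genome_layout")
  if (size <= 0) stop("window size must be > 0")
  if (step <= 0) stop("window step must be > 0")
  pieces <- lapply(seq_len(nrow(layout)), function(i) {
    len <- layout$length[i]
    starts <- seq(0, max(0, len - 1), by = step)
    starts <- starts[starts < len]
    data.frame(chrom = layout$chrom[i], start = starts,
               end = pmin(starts + size, len), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, pieces)
  out$window_id <- sprintf("%s:%d-%d", out$chrom, out$start, out$end)
  rownames(out) <- NULL
  out
}

#' Merge overlapping intervals
#'
#' Collapses a set of intervals into the minimal disjoint union (per
#' chromosome), used e.g. to build the differential-TAD region set.
#'
#' @param x Interval `data.frame`.
#' @return Disjoint, sorted interval `data.frame`.
#' @export
merge_intervals <- function(x) {
  if (nrow(x) == 0) return(x[, c("chrom", "start", "end")])
  from_granges(GenomicRanges::reduce(as_granges(x)))
}

# Indices of `query` intervals overlapping any `subject` interval by >= 1 bp.
overlaps_any_idx <- function(query, subject) {
  if (nrow(query) == 0 || nrow(subject) == 0) return(integer(0))
  hits <- GenomicRanges::findOverlaps(as_granges(query), as_granges(subject))
  sort(unique(S4Vectors::queryHits(hits)))
}

# Pairwise overlap hits between two interval frames (>= 1 bp).
overlap_hits <- function(query, subject) {
  if (nrow(query) == 0 || nrow(subject) == 0) {
    return(data.frame(query = integer(0), subject = integer(0),
                      width = numeric(0)))
  }
  qg <- as_granges(query); sg <- as_granges(subject)
  hits <- GenomicRanges::findOverlaps(qg, sg)
  ov <- GenomicRanges::pintersect(qg[S4Vectors::queryHits(hits)],
                                  sg[S4Vectors::subjectHits(hits)])
  data.frame(query = S4Vectors::queryHits(hits),
             subject = S4Vectors::subjectHits(hits),
             width = GenomicRanges::width(ov))
}

# Count, for each subject interval, the overlapping query intervals.
count_overlaps_in <- function(subject, query) {
  if (nrow(subject) == 0) return(integer(0))
  if (nrow(query) == 0) return(integer(nrow(subject)))
  GenomicRanges::countOverlaps(as_granges(subject), as_granges(query))
}
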