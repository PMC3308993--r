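# Circular-coordinate intervals.
#
# All internal coordinates are 0-based half-open [start, end); file readers
# and writers convert to/from the 1-based inclusive convention of
# GenBank/GFF3 at the boundary.  An interval may wrap across the origin of
# a circular sequence, in which case `wraps = TRUE` and end < start; its
# length is computed modulo the genome length.

#' Create a genomic interval
#'
#' Intervals are 0-based half-open.  On circular sequences an interval may
#' cross the origin (`wraps = TRUE`), in which case `end` is the half-open
#' endpoint after wrapping (so `end <= start` is allowed).
#'
#' @param start 0-based inclusive start.
#' @param end 0-based exclusive end.
#' @param wraps logical; does the interval cross the circular origin?
#' @return an object of class `pc_interval`.
#' @examples
#' pc_interval(0, 300)
#' pc_interval(95, 5, wraps = TRUE)   # crosses the origin of a circle
#' @export
pc_interval <- function(start, end, wraps = FALSE) {
  start <- as.integer(start); end <- as.integer(end)
  if (is.na(start) || is.na(end)) pc_stop("interval bounds must be finite")
  if (start < 0L || end < 0L) pc_stop("interval bounds must be >= 0")
  if (!wraps && end <= start)
    pc_stop("non-wrapping interval must have start < end (got [",
            start, ", ", end, "))")
  structure(list(start = start, end = end, wraps = isTRUE(wraps)),
            class = "pc_interval")
}

#' @export
print.pc_interval <- function(x, ...) {
  cat(sprintf("[%d, %d)%s\n", x$start, x$end,
              if (x$wraps) " (wraps origin)" else ""))
  invisible(x)
}

#' Interval length on a circle
#'
#' @param iv a `pc_interval`.
#' @param genome_length total sequence length (required for wrapping
#'   intervals).
#' @return integer length in bases, always > 0.
#' @export
iv_length <- function(iv, genome_length = NULL) {
  if (!iv$wraps) return(iv$end - iv$start)
  if (is.null(genome_length))
    pc_stop("genome_length required for a wrapping interval")
  genome_length - iv$start + iv$end
}

# 1-based positions covered by an interval, in order along the sequence.
iv_positions <- function(iv, genome_length) {
  if (!iv$wraps) return(seq.int(iv$start + 1L, iv$end))
  c(seq.int(iv$start + 1L, genome_length),
    if (iv$end > 0L) seq.int(1L, iv$end) else integer(0))
}

# Extract the bases of an interval from a sequence string.
iv_sequence <- function(seq, iv) {
  L <- nchar(seq)
  if (!iv$wraps) return(substr(seq, iv$start + 1L, iv$end))
  paste0(substr(seq, iv$start + 1L, L),
         if (iv$end > 0L) substr(seq, 1L, iv$end) else "")
}

# Does `outer` contain `inner` (both pc_interval) on a circle of length L?
iv_contains <- function(outer, inner, L) {
  pos_in <- function(p, iv) {
    if (!iv$wraps) p >= iv$start && p < iv$end
    else p >= iv$start || p < iv$end
  }
  # containment of half-open intervals: start inside and (end-1) inside,
  # and inner not longer than outer.
  if (iv_length(inner, L) > iv_length(outer, L)) return(FALSE)
  last <- (inner$end - 1L) %% L
  pos_in(inner$start, outer) && pos_in(last, outer)
}

# Convert a 1-based inclusive (GenBank/GFF) range to internal coordinates.
iv_from_one_based <- function(first, last, genome_length = NULL) {
  if (!is.null(genome_length) && last < first) {
    # wrapping range on a circle, e.g. 67000..500
    return(pc_interval(first - 1L, last, wraps = TRUE))
  }
  pc_interval(first - 1L, last)
}

# Convert back to 1-based inclusive (first, last).
iv_to_one_based <- function(iv) {
  c(first = iv$start + 1L, last = iv$end)
}
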