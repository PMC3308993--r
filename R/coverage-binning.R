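# Coverage-based selection of plastid contigs from a whole-genome
# assembly.  Organellar contigs in a total-DNA assembly share a
# characteristic fold-coverage set off from the nuclear background; given
# one or more homology-identified seed contigs, all contigs of "similar"
# coverage are selected.  "Similar" is operationalized as a symmetric
# fractional window around the seed coverages.

#' Select contigs by coverage similarity to seed contigs
#'
#' The acceptance window is
#' `[min(seed coverages) * (1 - tolerance), max(seed coverages) * (1 + tolerance)]`
#' (inclusive bounds).  Seeds are always selected; non-seed contigs are
#' selected when their coverage lies in the window and their length is at
#' least `min_len`.
#'
#' @param contigs `data.frame` with columns `id`, `length`, `coverage`
#'   and logical `seed` (homology-identified plastid contigs).
#' @param tolerance fractional window half-width (default 0.25).
#' @param min_len minimum contig length for non-seed selection
#'   (default 500).
#' @return character vector of selected contig ids, sorted by length
#'   descending (ties by id).
#' @export
select_by_coverage <- function(contigs, tolerance = 0.25, min_len = 500L) {
  need <- c("id", "length", "coverage", "seed")
  if (!all(need %in% names(contigs)))
    pc_stop("contigs needs columns ", paste(need, collapse = ", "))
  seed <- as.logical(contigs$seed)
  if (!any(seed)) pc_stop("no seed contigs given")
  if (any(contigs$length <= 0L) || any(contigs$coverage < 0))
    pc_stop("contig lengths must be > 0 and coverages >= 0")
  win <- c(min(contigs$coverage[seed]) * (1 - tolerance),
           max(contigs$coverage[seed]) * (1 + tolerance))
  hit <- seed | (contigs$coverage >= win[1L] & contigs$coverage <= win[2L] &
                   contigs$length >= min_len)
  sel <- contigs[hit, , drop = FALSE]
  sel$id[order(-sel$length, sel$id)]
}

#' Read a contig table
#'
#' TSV with columns `id`, `length`, `coverage` (and optionally `seed`).
#'
#' @param path TSV path.
#' @param seeds optional character vector of seed contig ids, overriding
#'   (or supplying) the `seed` column.
#' @return `data.frame` suitable for [select_by_coverage()].
#' @export
read_contig_table <- function(path, seeds = NULL) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("id", "length", "coverage") %in% names(tab)))
    pc_stop("expected columns id, length, coverage in ", path)
  if (!is.null(seeds)) {
    missing <- setdiff(seeds, tab$id)
    if (length(missing))
      pc_stop("seed id(s) not in table: ", paste(missing, collapse = ", "))
    tab$seed <- tab$id %in% seeds
  } else if (is.null(tab$seed)) {
    tab$seed <- FALSE
  } else {
    tab$seed <- as.logical(tab$seed)
  }
  tab
}
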