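# Core data model: gene features and annotated genomes.

FEATURE_TYPES <- c("CDS", "tRNA", "rRNA")

#' Create a gene feature
#'
#' A feature is one annotated locus (CDS, tRNA or rRNA) with one or more
#' exon segments in transcription order; more than one segment encodes
#' intron(s).  Gene names are normalized on construction (see
#' [normalize_gene_name()]); features whose normalized name matches the
#' unnamed-ORF pattern `orf<digits>` are flagged non-conserved.
#'
#' @param raw_name gene label as annotated.
#' @param ftype one of `"CDS"`, `"tRNA"`, `"rRNA"`.
#' @param strand `"+"` or `"-"`.
#' @param segments list of [pc_interval()] in transcription order.
#' @param name normalized name; computed from `raw_name` when `NULL`.
#' @param synonyms optional synonym table passed to [normalize_gene_name()].
#' @return an object of class `gene_feature`.
#' @export
gene_feature <- function(raw_name, ftype, strand, segments, name = NULL,
                         synonyms = NULL) {
  ftype <- match.arg(ftype, FEATURE_TYPES)
  if (!strand %in% c("+", "-")) pc_stop("strand must be '+' or '-'")
  if (!is.list(segments) || length(segments) < 1L)
    pc_stop("segments must be a non-empty list of intervals")
  if (inherits(segments, "pc_interval")) segments <- list(segments)
  if (is.null(name)) name <- normalize_gene_name(raw_name, synonyms)
  structure(list(
    raw_name = raw_name,
    name = name,
    ftype = ftype,
    strand = strand,
    segments = segments,
    conserved = !grepl("^orf[0-9]+$", name)
  ), class = "gene_feature")
}

#' @export
print.gene_feature <- function(x, ...) {
  segs <- vapply(x$segments, function(s)
    sprintf("[%d,%d)%s", s$start, s$end, if (s$wraps) "~" else ""), "")
  cat(sprintf("%s %s (%s) strand %s, %d segment(s): %s\n",
              x$ftype, x$name, x$raw_name, x$strand,
              length(x$segments), paste(segs, collapse = " ")))
  invisible(x)
}

#' Create an annotated genome
#'
#' @param id accession or free-text identifier.
#' @param sequence nucleotide string (IUPAC alphabet).
#' @param topology `"circular"` or `"linear"`.
#' @param features list of [gene_feature()] objects.
#' @return an object of class `annotated_genome`.
#' @export
annotated_genome <- function(id, sequence, topology = c("circular", "linear"),
                             features = list()) {
  topology <- match.arg(topology)
  sequence <- toupper(sequence)
  L <- nchar(sequence)
  if (L < 1L) pc_stop("genome '", id, "' has an empty sequence")
  for (f in features) {
    for (s in f$segments) {
      if (s$start >= L || s$end > L)
        pc_stop("feature '", f$name, "' lies outside the sequence (length ",
                L, ")")
      if (s$wraps && topology != "circular")
        pc_stop("feature '", f$name, "' wraps the origin of a linear genome")
    }
  }
  structure(list(id = id, sequence = sequence, topology = topology,
                 features = features),
            class = "annotated_genome")
}

#' @export
print.annotated_genome <- function(x, ...) {
  tab <- table(factor(vapply(x$features, `[[`, "", "ftype"),
                      levels = FEATURE_TYPES))
  cat(sprintf("annotated_genome '%s': %s, %d bp, %d features (%s)\n",
              x$id, x$topology, nchar(x$sequence), length(x$features),
              paste(sprintf("%s %d", names(tab), tab), collapse = ", ")))
  invisible(x)
}

#' Genome length in bases
#' @param genome an `annotated_genome`.
#' @return integer length.
#' @export
genome_length <- function(genome) nchar(genome$sequence)

# ---- per-feature geometry ----------------------------------------------

# Genomic span of a feature: from the first base of its first genomic
# segment to the last base of its last genomic segment.  Segments are in
# transcription order, so on the minus strand the genomic order is the
# reverse.
feature_span <- function(f, L = NULL) {
  segs <- f$segments
  if (length(segs) == 1L) return(segs[[1L]])
  if (any(vapply(segs, `[[`, TRUE, "wraps"))) {
    if (is.null(L)) pc_stop("genome length needed for wrapping feature span")
    # span from genomic start of the segment chain to its genomic end,
    # walking in transcription order (or its reverse on the minus strand)
    if (f$strand == "-") segs <- rev(segs)
    first <- segs[[1L]]; last <- segs[[length(segs)]]
    return(pc_interval(first$start, last$end,
                       wraps = last$end <= first$start))
  }
  starts <- vapply(segs, `[[`, 0L, "start")
  ends <- vapply(segs, `[[`, 0L, "end")
  pc_interval(min(starts), max(ends))
}

exon_bases <- function(f, L = NULL) {
  sum(vapply(f$segments, iv_length, 0L, genome_length = L))
}

intron_bases <- function(f, L = NULL) {
  iv_length(feature_span(f, L), L) - exon_bases(f, L)
}

# Per-base coverage counts over all feature spans (introns included).
coverage_counts <- function(genome) {
  L <- genome_length(genome)
  cov <- integer(L)
  for (f in genome$features) {
    p <- iv_positions(feature_span(f, L), L)
    cov[p] <- cov[p] + 1L
  }
  cov
}

# ---- gene-name normalization -------------------------------------------

AA3TO1 <- c(Ala = "A", Arg = "R", Asn = "N", Asp = "D", Cys = "C",
            Gln = "Q", Glu = "E", Gly = "G", His = "H", Ile = "I",
            Leu = "L", Lys = "K", Met = "M", Phe = "F", Pro = "P",
            Ser = "S", Thr = "T", Trp = "W", Tyr = "Y", Val = "V",
            fMet = "M", Sec = "U")

#' Load the packaged gene-synonym table
#'
#' Two-column TSV (`alias`, `canonical`).  Users can supply their own
#' table to [normalize_gene_name()]; the packaged one maps, at minimum,
#' `ycf13` to `mat1` and `rpl3` to `ycf65` (the same putative ribosomal
#' protein has been annotated under both labels in different plastid
#' genomes).
#'
#' @param path optional path to a user TSV with the same two columns.
#' @return named character vector (alias -> canonical), aliases lower-case.
#' @export
load_synonyms <- function(path = NULL) {
  if (is.null(path)) {
    cached <- get0("default_synonyms", envir = .pc_cache)
    if (!is.null(cached)) return(cached)
    path <- system.file("extdata", "gene_synonyms.tsv",
                        package = "plastidcomp", mustWork = TRUE)
    tab <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                             comment.char = "#")
    out <- stats::setNames(tab$canonical, tolower(tab$alias))
    assign("default_synonyms", out, envir = .pc_cache)
    return(out)
  }
  tab <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                           comment.char = "#")
  stats::setNames(tab$canonical, tolower(tab$alias))
}

.pc_cache <- new.env(parent = emptyenv())

#' Normalize a gene name
#'
#' Applies conventional gene casing (lower-case with a capitalized final
#' letter for purely alphabetic names such as `psbA`, `rpoB`, `ccsA`),
#' canonicalizes tRNA labels to `trn<AA>` / `trn<AA>-<anticodon>` where the
#' amino acid (and optionally the anticodon) can be parsed, and applies a
#' synonym table mapping aliases to one canonical label.  Unnamed ORFs
#' (`orf<digits>`) pass through unchanged.  The function is idempotent and
#' always returns a label.
#'
#' @param raw character vector of annotated labels.
#' @param synonyms named character vector as returned by [load_synonyms()];
#'   defaults to the packaged table.
#' @return character vector of normalized labels.
#' @examples
#' normalize_gene_name(c("PsbA", "ycf13", "orf248", "tRNA-Ala(ugc)"))
#' @export
normalize_gene_name <- function(raw, synonyms = NULL) {
  if (is.null(synonyms)) synonyms <- load_synonyms()
  vapply(raw, function(x) normalize_one(x, synonyms), "", USE.NAMES = FALSE)
}

normalize_one <- function(x, synonyms) {
  x <- trimws(x)
  if (!nzchar(x)) return("unnamed")
  low <- tolower(x)

  # tRNAs: accept "tRNA-Ala", "tRNA-Ala(ugc)", "trnA-UGC", "trnA" ...
  m <- regmatches(low, regexec(
    "^trna[-_ ]([a-z]{3,4})[-_ (]*([acgut]{3})?\\)?$", low))[[1L]]
  if (length(m)) {
    idx <- which(tolower(names(AA3TO1)) == m[2L])
    if (length(idx) == 1L)
      return(trn_label(AA3TO1[[idx]], m[3L]))
  }
  m <- regmatches(x, regexec(
    "^[Tt][Rr][Nn]([A-Za-z])([-_ ]([ACGUTacgut]{3}))?$", x))[[1L]]
  if (length(m))
    return(trn_label(toupper(m[2L]), m[4L]))

  # unnamed ORFs pass through (flagged non-conserved by gene_feature())
  if (grepl("^orf[0-9]+$", low)) return(low)

  # conventional casing: names with >= 4 leading letters get the final
  # letter capitalized, keeping any trailing digits (psbA, rpoB, ccsA,
  # rpoC1); short-prefix names with digits (rpl2, ycf13, mat1, rrn16)
  # stay lower-case.
  m <- regmatches(low, regexec("^([a-z]{3,})([a-z])([0-9]*)$", low))[[1L]]
  name <- if (length(m)) paste0(m[2L], toupper(m[3L]), m[4L]) else low

  canon <- unname(synonyms[tolower(name)])
  if (length(canon) == 1L && !is.na(canon)) canon else name
}

trn_label <- function(aa, anticodon) {
  if (!is.na(anticodon) && nzchar(anticodon %||% ""))
    paste0("trn", aa, "-", toupper(chartr("Tt", "Uu", anticodon)))
  else paste0("trn", aa)
}

# ---- reverse complement -------------------------------------------------

#' Reverse complement of a nucleotide string
#'
#' IUPAC-aware reverse complement (via Biostrings); `N` maps to `N`.
#'
#' @param seq single nucleotide string.
#' @return reverse-complemented string.
#' @examples
#' reverse_complement("AAAC")  # "GTTT"
#' @export
reverse_complement <- function(seq) {
  out <- tryCatch(
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq))),
    error = function(e) pc_stop("non-IUPAC character in sequence: ",
                                conditionMessage(e)))
  out
}
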