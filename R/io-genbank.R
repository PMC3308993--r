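# GenBank flat-file input/output.
#
# There is no GenBank parser among the package's Bioconductor dependencies,
# so a minimal reader for the flat-file format is implemented here: LOCUS
# topology, CDS/tRNA/rRNA features with join()/complement() locations, and
# the ORIGIN sequence block.  This is sufficient for annotated organellar
# records and for round-tripping the simulator's output.

#' Read an annotated genome from a GenBank flat file
#'
#' Parses the LOCUS line (topology; defaults to circular when flagged),
#' all CDS/tRNA/rRNA features (compound `join()` locations become
#' multi-segment features; `complement()` sets the strand, with segments
#' stored in transcription order) and the ORIGIN sequence.  On circular
#' records a final location pair `a..L,1..b` is folded into a single
#' origin-wrapping segment.
#'
#' @param path path to a GenBank flat file.
#' @param synonyms optional synonym table (see [load_synonyms()]).
#' @return an [annotated_genome()].
#' @export
read_genbank <- function(path, synonyms = NULL) {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines)) pc_stop("empty file: ", path)
  if (is.null(synonyms)) synonyms <- load_synonyms()

  locus <- grep("^LOCUS", lines, value = TRUE)
  if (!length(locus)) pc_stop("no LOCUS line in ", path)
  topology <- if (grepl("\\bcircular\\b", locus[1L], ignore.case = TRUE))
    "circular" else "linear"
  id <- strsplit(trimws(sub("^LOCUS", "", locus[1L])), "\\s+")[[1L]][1L]
  acc <- grep("^ACCESSION", lines, value = TRUE)
  if (length(acc)) {
    a <- strsplit(trimws(sub("^ACCESSION", "", acc[1L])), "\\s+")[[1L]][1L]
    if (!is.na(a) && nzchar(a)) id <- a
  }

  # sequence
  ori <- grep("^ORIGIN", lines)
  if (!length(ori)) pc_stop("record has no ORIGIN sequence block: ", path)
  endrec <- grep("^//", lines)
  endrec <- if (length(endrec)) endrec[endrec > ori[1L]][1L] else length(lines) + 1L
  seq_lines <- lines[seq.int(ori[1L] + 1L, endrec - 1L)]
  sequence <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))
  if (!nzchar(sequence)) pc_stop("record has an empty sequence: ", path)
  L <- nchar(sequence)

  # features
  fstart <- grep("^FEATURES", lines)
  features <- list()
  if (length(fstart)) {
    flines <- lines[seq.int(fstart[1L] + 1L, ori[1L] - 1L)]
    features <- parse_genbank_features(flines, L, topology, synonyms)
  }
  annotated_genome(id, sequence, topology, features)
}

parse_genbank_features <- function(flines, L, topology, synonyms) {
  # a feature header has a non-blank feature key in columns 6-20
  keys <- substr(flines, 6L, 20L)
  is_header <- nzchar(trimws(keys)) & !grepl("^\\s*/", flines)
  idx <- which(is_header)
  out <- list()
  for (i in seq_along(idx)) {
    key <- trimws(keys[idx[i]])
    if (!key %in% FEATURE_TYPES) next
    to <- if (i < length(idx)) idx[i + 1L] - 1L else length(flines)
    block <- flines[seq.int(idx[i], to)]
    body <- trimws(substring(block, 22L))
    # location: first line(s) up to the first qualifier
    qual_at <- grep("^/", body)
    loc_end <- if (length(qual_at)) qual_at[1L] - 1L else length(body)
    loc <- paste(body[seq_len(loc_end)], collapse = "")
    quals <- body[seq_along(body) > loc_end]
    raw_name <- genbank_qualifier(quals, "gene") %||%
      genbank_qualifier(quals, "standard_name") %||%
      genbank_qualifier(quals, "product") %||%
      genbank_qualifier(quals, "locus_tag") %||% "unnamed"
    parsed <- parse_genbank_location(loc, L, topology)
    segs <- parsed$segments
    if (parsed$strand == "-") segs <- rev(segs)  # transcription order
    out[[length(out) + 1L]] <-
      gene_feature(raw_name, key, parsed$strand, segs, synonyms = synonyms)
  }
  out
}

genbank_qualifier <- function(quals, what) {
  hit <- grep(paste0("^/", what, "="), quals, value = TRUE)
  if (!length(hit)) return(NULL)
  gsub("^\"|\"$", "", sub(paste0("^/", what, "="), "", hit[1L]))
}

parse_genbank_location <- function(loc, L, topology) {
  loc <- gsub("\\s", "", loc)
  strand <- "+"
  if (grepl("^complement\\(", loc)) {
    strand <- "-"
    loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
  }
  loc <- sub("^(join|order)\\((.*)\\)$", "\\2", loc)
  parts <- strsplit(loc, ",")[[1L]]
  ranges <- lapply(parts, function(p) {
    p <- gsub("[<>]", "", p)
    if (grepl("\\.\\.", p)) {
      ab <- as.integer(strsplit(p, "\\.\\.")[[1L]])
    } else {
      ab <- rep(as.integer(p), 2L)
    }
    if (any(is.na(ab))) pc_stop("unparseable location: ", loc)
    ab
  })
  # fold a..L,1..b (circular origin crossing) into one wrapping segment
  segments <- list()
  i <- 1L
  while (i <= length(ranges)) {
    r <- ranges[[i]]
    if (topology == "circular" && i < length(ranges) &&
        r[2L] == L && ranges[[i + 1L]][1L] == 1L) {
      nxt <- ranges[[i + 1L]]
      segments[[length(segments) + 1L]] <-
        pc_interval(r[1L] - 1L, nxt[2L], wraps = TRUE)
      i <- i + 2L
    } else {
      segments[[length(segments) + 1L]] <- iv_from_one_based(r[1L], r[2L], L)
      i <- i + 1L
    }
  }
  list(strand = strand, segments = segments)
}

#' Write an annotated genome as a GenBank flat file
#'
#' The inverse of [read_genbank()]: emits a LOCUS line carrying the
#' topology, one feature per CDS/tRNA/rRNA with `/gene` qualifier, and the
#' ORIGIN sequence block.  Output is byte-deterministic (fixed date
#' field), so identical genomes serialize identically.
#'
#' @param genome an [annotated_genome()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_genbank <- function(genome, path) {
  L <- genome_length(genome)
  con <- file(path, "w")
  on.exit(close(con))
  name <- gsub("\\s", "_", genome$id)
  writeLines(sprintf("LOCUS       %-16s %d bp    DNA     %-8s PLN 01-JAN-2000",
                     substr(name, 1L, 16L), L, genome$topology), con)
  writeLines(sprintf("DEFINITION  %s, %s genome.", genome$id, genome$topology),
             con)
  writeLines(sprintf("ACCESSION   %s", name), con)
  writeLines("FEATURES             Location/Qualifiers", con)
  writeLines(sprintf("     source          1..%d", L), con)
  for (f in genome$features) {
    writeLines(sprintf("     %-15s %s", f$ftype, genbank_location(f, L)), con)
    writeLines(sprintf("                     /gene=\"%s\"", f$raw_name), con)
  }
  writeLines("ORIGIN", con)
  writeLines(format_origin(genome$sequence), con)
  writeLines("//", con)
  invisible(path)
}

genbank_location <- function(f, L) {
  segs <- f$segments
  if (f$strand == "-") segs <- rev(segs)  # back to genomic order
  parts <- unlist(lapply(segs, function(s) {
    if (s$wraps) c(sprintf("%d..%d", s$start + 1L, L),
                   sprintf("1..%d", s$end))
    else sprintf("%d..%d", s$start + 1L, s$end)
  }))
  loc <- if (length(parts) > 1L)
    sprintf("join(%s)", paste(parts, collapse = ",")) else parts
  if (f$strand == "-") sprintf("complement(%s)", loc) else loc
}

format_origin <- function(sequence) {
  L <- nchar(sequence)
  starts <- seq.int(1L, L, by = 60L)
  vapply(starts, function(s) {
    chunk <- substr(sequence, s, min(s + 59L, L))
    blocks <- substring(chunk, seq(1L, nchar(chunk), 10L),
                        pmin(seq(10L, nchar(chunk) + 9L, 10L), nchar(chunk)))
    sprintf("%9d %s", s, tolower(paste(blocks, collapse = " ")))
  }, "")
}
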