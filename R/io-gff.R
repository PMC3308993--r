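# GFF3 + FASTA input/output.

#' Read an annotated genome from GFF3 + FASTA
#'
#' GFF3 coordinates are 1-based inclusive and converted to the internal
#' 0-based half-open convention at the boundary.  Rows of type CDS, tRNA
#' and rRNA become features; rows sharing an `ID` attribute become one
#' multi-segment feature (introns); structural container rows (`gene`,
#' `region`, `exon`, `source`) are ignored silently, any other type with a
#' warning.  On circular genomes a segment pair `a..L, 1..b` under one ID
#' is folded into a single origin-wrapping segment.
#'
#' @param gff path to a GFF3 file.
#' @param fasta path to the matching FASTA file (single sequence).
#' @param topology `"circular"` (default) or `"linear"`.
#' @param synonyms optional synonym table (see [load_synonyms()]).
#' @return an [annotated_genome()].
#' @export
read_gff_fasta <- function(gff, fasta, topology = "circular",
                           synonyms = NULL) {
  if (is.null(synonyms)) synonyms <- load_synonyms()
  seqs <- Biostrings::readDNAStringSet(fasta)
  if (length(seqs) != 1L)
    pc_stop("expected exactly one sequence in ", fasta, ", found ",
            length(seqs))
  seq_id <- strsplit(names(seqs)[1L], "\\s+")[[1L]][1L]
  sequence <- as.character(seqs[[1L]])
  L <- nchar(sequence)

  lines <- readLines(gff, warn = FALSE)
  lines <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  if (length(lines)) {
    tab <- utils::read.delim(text = lines, header = FALSE,
                             stringsAsFactors = FALSE,
                             col.names = c("seqid", "source", "type", "start",
                                           "end", "score", "strand", "phase",
                                           "attributes"))
  } else {
    tab <- data.frame(seqid = character(), type = character(),
                      start = integer(), end = integer(),
                      strand = character(), attributes = character())
  }
  if (nrow(tab)) {
    bad <- setdiff(unique(tab$seqid), seq_id)
    if (length(bad))
      pc_stop("GFF sequence ID(s) ", paste(bad, collapse = ", "),
              " do not match FASTA sequence '", seq_id, "'")
    silent <- c("gene", "region", "exon", "source", "mRNA", "chromosome")
    unknown <- setdiff(unique(tab$type), c(FEATURE_TYPES, silent))
    if (length(unknown))
      pc_warn("ignoring unknown GFF feature type(s): ",
              paste(unknown, collapse = ", "))
    tab <- tab[tab$type %in% FEATURE_TYPES, , drop = FALSE]
  }

  features <- list()
  if (nrow(tab)) {
    ids <- vapply(tab$attributes, gff_attr, "", what = "ID")
    ids[!nzchar(ids)] <- paste0(".row", which(!nzchar(ids)))
    for (g in unique(ids)) {
      rows <- tab[ids == g, , drop = FALSE]
      raw_name <- gff_attr(rows$attributes[1L], "Name")
      if (!nzchar(raw_name)) raw_name <- gff_attr(rows$attributes[1L], "gene")
      if (!nzchar(raw_name)) raw_name <- g
      strand <- rows$strand[1L]
      if (!strand %in% c("+", "-")) strand <- "+"
      ranges <- lapply(seq_len(nrow(rows)),
                       function(i) c(rows$start[i], rows$end[i]))
      segs <- fold_wrapping(ranges, L, topology)
      if (strand == "-") segs <- rev(segs)  # transcription order
      features[[length(features) + 1L]] <-
        gene_feature(raw_name, rows$type[1L], strand, segs,
                     synonyms = synonyms)
    }
  }
  annotated_genome(seq_id, sequence, topology, features)
}

gff_attr <- function(attrs, what) {
  m <- regmatches(attrs, regexec(paste0("(^|;)\\s*", what, "=([^;]+)"),
                                 attrs))[[1L]]
  if (length(m)) utils::URLdecode(m[3L]) else ""
}

fold_wrapping <- function(ranges, L, topology) {
  segments <- list()
  i <- 1L
  while (i <= length(ranges)) {
    r <- ranges[[i]]
    if (topology == "circular" && i < length(ranges) &&
        r[2L] == L && ranges[[i + 1L]][1L] == 1L) {
      segments[[length(segments) + 1L]] <-
        pc_interval(r[1L] - 1L, ranges[[i + 1L]][2L], wraps = TRUE)
      i <- i + 2L
    } else {
      segments[[length(segments) + 1L]] <- iv_from_one_based(r[1L], r[2L], L)
      i <- i + 1L
    }
  }
  segments
}

#' Write an annotated genome as GFF3 + FASTA
#'
#' @param genome an [annotated_genome()].
#' @param gff output GFF3 path.
#' @param fasta output FASTA path.
#' @return `gff`, invisibly.
#' @export
write_gff_fasta <- function(genome, gff, fasta) {
  L <- genome_length(genome)
  lines <- c("##gff-version 3",
             sprintf("##sequence-region %s 1 %d", genome$id, L))
  for (i in seq_along(genome$features)) {
    f <- genome$features[[i]]
    fid <- sprintf("%s.%03d", f$name, i)
    segs <- f$segments
    if (f$strand == "-") segs <- rev(segs)  # genomic order in the file
    phase_cum <- 0L
    for (s in segs) {
      ranges <- if (s$wraps)
        list(c(s$start + 1L, L), c(1L, s$end))
      else list(c(s$start + 1L, s$end))
      for (r in ranges) {
        phase <- if (f$ftype == "CDS") as.character(phase_cum %% 3L) else "."
        lines <- c(lines, paste(
          genome$id, "plastidcomp", f$ftype, r[1L], r[2L], ".", f$strand,
          phase, sprintf("ID=%s;Name=%s", fid, f$raw_name), sep = "\t"))
        phase_cum <- (phase_cum + (r[2L] - r[1L] + 1L)) %% 3L
      }
    }
  }
  writeLines(lines, gff)
  seqs <- Biostrings::DNAStringSet(genome$sequence)
  names(seqs) <- genome$id
  Biostrings::writeXStringSet(seqs, fasta, width = 70L)
  invisible(gff)
}
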