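# Per-genome feature summaries (the "general features" table of a
# comparative plastid-genome study: size, GC, gene counts, intron content,
# density, coding fraction, intergenic and overlapping bases).

#' GC percentage of a genome
#'
#' 100 x (G + C) / length, case-insensitive.  Ambiguity codes (including
#' N) count in the denominator only.  Reported rounded half-up to two
#' decimals.
#'
#' @param genome an [annotated_genome()] or a plain nucleotide string.
#' @return GC percentage (two decimals).
#' @examples
#' gc_percentage("ACGT")  # 50
#' @export
gc_percentage <- function(genome) {
  seq <- if (inherits(genome, "annotated_genome")) genome$sequence
         else toupper(genome)
  if (!nzchar(seq)) pc_stop("empty sequence")
  gc <- Biostrings::letterFrequency(Biostrings::DNAString(seq), "GC")
  round_half_up(100 * as.numeric(gc) / nchar(seq), 2)
}

#' Summarize the general features of an annotated genome
#'
#' Computes one row of the per-genome feature table: genome size, GC
#' percentage, gene-unique loci (CDS + tRNA + rRNA after collapsing
#' inverted-repeat duplicates), unique rRNA/tRNA counts with total bases
#' over all copies, conserved/all CDS counts, spliced/non-spliced CDS
#' counts and bases, intron count and bases, gene density per kb, average
#' CDS length excluding introns, coding percentage excluding introns,
#' intergenic bases and overlapping bases.
#'
#' Conventions (documented because the published tables do not define
#' them): "unique" loci collapse only IR-resident duplicates - two loci
#' collapse when both lie within the IR intervals of `ir` and share
#' normalized name and feature type; rRNA/tRNA total bases sum over all
#' copies; average CDS length is floor-rounded; intergenic bases are the
#' bases covered by no feature span at all; overlapping bases are covered
#' by two or more feature spans, counted once.
#'
#' @param genome an [annotated_genome()].
#' @param ir optional [partition_quadripartite()] result used to collapse
#'   IR-resident duplicate loci.
#' @return a one-row `data.frame` (class `summary_row`).
#' @export
summarize_genome <- function(genome, ir = NULL) {
  L <- genome_length(genome)
  feats <- genome$features
  ftypes <- vapply(feats, `[[`, "", "ftype")
  names_ <- vapply(feats, `[[`, "", "name")

  if (!is.null(ir)) {
    for (iv in list(ir$ira, ir$irb)) {
      last <- (iv$end - 1L) %% L
      if (iv$start >= L || last >= L)
        pc_stop("IR intervals outside the genome")
    }
  }

  dup_idx <- ir_duplicate_indices(feats, ir, L)
  gene_unique_loci <- length(feats) - length(dup_idx)

  by_type <- function(type) which(ftypes == type)
  cds_i <- by_type("CDS"); trna_i <- by_type("tRNA"); rrna_i <- by_type("rRNA")

  exon <- vapply(feats, exon_bases, 0L, L = L)
  intr <- vapply(feats, intron_bases, 0L, L = L)
  nseg <- vapply(feats, function(f) length(f$segments), 0L)
  conserved <- vapply(feats, `[[`, TRUE, "conserved")

  uniq_species <- function(i) length(unique(names_[i]))
  cds_all <- length(cds_i)
  spliced_i <- cds_i[nseg[cds_i] > 1L]
  nonspliced_i <- cds_i[nseg[cds_i] == 1L]

  cov <- coverage_counts(genome)
  cds_exon_total <- sum(exon[cds_i])

  row <- data.frame(
    id = genome$id,
    genome_size = L,
    gc_percentage = gc_percentage(genome),
    gene_unique_loci = gene_unique_loci,
    rrna_unique_count = uniq_species(rrna_i),
    rrna_total_bases = sum(exon[rrna_i]),
    trna_unique_count = uniq_species(trna_i),
    trna_total_bases = sum(exon[trna_i]),
    cds_conserved = sum(conserved[cds_i]),
    cds_all = cds_all,
    nonspliced_count = length(nonspliced_i),
    nonspliced_bases = sum(exon[nonspliced_i]),
    spliced_count = length(spliced_i),
    spliced_bases = sum(exon[spliced_i]),
    intron_count = sum(nseg[cds_i] - 1L),
    intron_bases = sum(intr[cds_i]),
    density = round_half_up(cds_all / (L / 1000), 3),
    avg_len_excl_introns = if (cds_all) floor(cds_exon_total / cds_all) else 0L,
    coding_pct_excl_introns = round_half_up(100 * cds_exon_total / L, 1),
    intergenic_bases_excl_rna = sum(cov == 0L),
    overlapping_bases = sum(cov >= 2L),
    stringsAsFactors = FALSE
  )
  class(row) <- c("summary_row", class(row))
  row
}

# Indices of features that are IR-duplicate copies (the copy in the
# higher-start IR interval of each duplicated pair), or integer(0) when no
# partition is supplied.
ir_duplicate_indices <- function(feats, ir, L) {
  if (is.null(ir) || !length(feats)) return(integer(0))
  in_iv <- function(iv) which(vapply(feats, function(f)
    iv_contains(iv, feature_span(f, L), L), TRUE))
  a <- in_iv(ir$ira); b <- in_iv(ir$irb)
  key <- function(i) paste(vapply(feats[i], `[[`, "", "name"),
                           vapply(feats[i], `[[`, "", "ftype"))
  dup <- integer(0)
  used_a <- logical(length(a))
  for (j in seq_along(b)) {
    m <- which(!used_a & key(a) == key(b[j]))
    if (length(m)) {
      used_a[m[1L]] <- TRUE
      dup <- c(dup, b[j])
    }
  }
  dup
}
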