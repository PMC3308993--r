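# Gene-content set algebra and the endosymbiotic gene-fate classifier.

#' Gene-content partition across genomes
#'
#' Exact set partition of the union of gene names over all 2^k - 1
#' membership regions of k genomes (k between 2 and 4).  Duplicate
#' normalized names within one genome collapse to one (with a message).
#'
#' @param genomes named list of 2-4 [annotated_genome()] objects, or of
#'   character vectors of normalized gene names.
#' @param protein_only consider CDS genes only (default TRUE; ignored for
#'   character-vector input).
#' @return named list of class `content_partition`: one sorted character
#'   vector per region, named by the genome names joined with `&` (e.g.
#'   `"A"`, `"A&B"`).  Regions are pairwise disjoint and their union is
#'   the union of the input sets.
#' @export
content_partition <- function(genomes, protein_only = TRUE) {
  k <- length(genomes)
  if (k < 2L || k > 4L) pc_stop("content_partition takes 2-4 genomes")
  if (is.null(names(genomes)) || any(!nzchar(names(genomes))))
    names(genomes) <- LETTERS[seq_len(k)]
  sets <- lapply(genomes, function(g) {
    if (is.character(g)) return(unique(g))
    feats <- g$features
    if (protein_only)
      feats <- feats[vapply(feats, `[[`, "", "ftype") == "CDS"]
    nm <- vapply(feats, `[[`, "", "name")
    if (anyDuplicated(nm))
      message("collapsing duplicate gene name(s) in '", g$id, "': ",
              paste(unique(nm[duplicated(nm)]), collapse = ", "))
    unique(nm)
  })
  all_genes <- sort(unique(unlist(sets)))
  member <- vapply(sets, function(s) all_genes %in% s,
                   logical(length(all_genes)))
  if (length(all_genes) == 1L) member <- matrix(member, nrow = 1L)
  sig <- apply(member, 1L, function(row)
    paste(names(sets)[row], collapse = "&"))
  out <- split(all_genes, sig)
  # order regions: single sets first, then pairs, etc.
  depth <- lengths(strsplit(names(out), "&", fixed = TRUE))
  out <- out[order(depth, names(out))]
  structure(out, class = c("content_partition", "list"))
}

#' Classify the fate of plastid genes relative to an algal reference
#'
#' For each gene of the reference set (the plastid genome of the closest
#' extant algal relative), membership in the descendant plastid gene sets
#' and presence in per-lineage transcriptome evidence decide its fate:
#'
#' * present in all plastid sets: `retained_plastid`;
#' * present in a proper nonempty subset: `lost_post_split` (lost in the
#'   lacking lineages after their divergence);
#' * absent from all plastid sets: `transferred_ancestral_both` when
#'   transcript evidence is positive in all sources,
#'   `transferred_ancestral_lost_in_one` when positive in a proper
#'   nonempty subset, `lost_completely` when positive in none.
#'
#' Genes in a plastid set but not in the reference are reported as
#' `lineage_specific_gain`.  Transcript evidence is an input table, not a
#' computed homology search, so the classifier is testable offline;
#' "lost completely" should be read as "probably lost" - transcripts may
#' also be missed by transcriptome sequencing.
#'
#' @param reference character vector of normalized reference gene names.
#' @param plastid_sets named list (>= 2) of character vectors of
#'   normalized gene names, one per descendant lineage.
#' @param evidence data.frame with columns `gene`, `source`, `present`
#'   (0/1 or logical); `source` values must be exactly the names of
#'   `plastid_sets`.  Rows for unknown genes are ignored with a warning.
#' @return a `data.frame` of class `fate_report` with columns `gene`,
#'   `fate`, `evidence` (comma-separated positive sources), `lineages`
#'   (comma-separated plastid sets containing the gene).
#' @export
classify_fates <- function(reference, plastid_sets, evidence = NULL) {
  if (length(plastid_sets) < 2L || is.null(names(plastid_sets)))
    pc_stop("plastid_sets must be a named list of >= 2 gene sets")
  sources <- names(plastid_sets)
  plastid_sets <- lapply(plastid_sets, unique)
  reference <- unique(reference)

  if (is.null(evidence))
    evidence <- data.frame(gene = character(0), source = character(0),
                           present = logical(0))
  if (!all(c("gene", "source", "present") %in% names(evidence)))
    pc_stop("evidence needs columns gene, source, present")
  bad_src <- setdiff(unique(evidence$source), sources)
  if (length(bad_src))
    pc_stop("evidence sources not matching any plastid set: ",
            paste(bad_src, collapse = ", "))
  all_known <- union(reference, unlist(plastid_sets))
  unk <- setdiff(unique(evidence$gene), all_known)
  if (length(unk)) {
    pc_warn("ignoring evidence rows for unknown gene(s): ",
            paste(unk, collapse = ", "))
    evidence <- evidence[!evidence$gene %in% unk, , drop = FALSE]
  }
  evidence <- evidence[as.logical(evidence$present), , drop = FALSE]
  pos_sources <- function(g)
    sort(unique(evidence$source[evidence$gene == g]))

  genes <- sort(union(reference, unlist(plastid_sets)))
  rows <- lapply(genes, function(g) {
    in_sets <- sources[vapply(plastid_sets, function(s) g %in% s, TRUE)]
    ev <- pos_sources(g)
    fate <- if (!g %in% reference) {
      "lineage_specific_gain"
    } else if (length(in_sets) == length(sources)) {
      "retained_plastid"
    } else if (length(in_sets) > 0L) {
      "lost_post_split"
    } else if (length(ev) == length(sources) && length(sources) > 0L) {
      "transferred_ancestral_both"
    } else if (length(ev) > 0L) {
      "transferred_ancestral_lost_in_one"
    } else {
      "lost_completely"
    }
    data.frame(gene = g, fate = fate,
               evidence = paste(ev, collapse = ","),
               lineages = paste(in_sets, collapse = ","),
               stringsAsFactors = FALSE)
  })
  rep_ <- do.call(rbind, rows)
  class(rep_) <- c("fate_report", class(rep_))
  rep_
}

#' Count fates in a fate report
#'
#' @param report a [classify_fates()] result.
#' @return named integer vector over all six fate categories.
#' @export
fate_counts <- function(report) {
  lv <- c("retained_plastid", "transferred_ancestral_both",
          "transferred_ancestral_lost_in_one", "lost_completely",
          "lost_post_split", "lineage_specific_gain")
  table(factor(report$fate, levels = lv))
}

#' Threshold a tabular homology-search hit file into an evidence table
#'
#' Reads a TSV of (query gene, source, e-value) rows - e.g. exported from
#' a transcriptome search - and thresholds it into the presence/absence
#' evidence table consumed by [classify_fates()].
#'
#' @param path TSV with columns `gene`, `source`, `evalue`.
#' @param max_evalue inclusion threshold (default 1e-10).
#' @param synonyms optional synonym table for gene-name normalization.
#' @return evidence `data.frame` (`gene`, `source`, `present`).
#' @export
read_search_evidence <- function(path, max_evalue = 1e-10, synonyms = NULL) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("gene", "source", "evalue") %in% names(tab)))
    pc_stop("expected columns gene, source, evalue in ", path)
  tab$gene <- normalize_gene_name(tab$gene, synonyms)
  agg <- stats::aggregate(evalue ~ gene + source, data = tab, FUN = min)
  data.frame(gene = agg$gene, source = agg$source,
             present = agg$evalue <= max_evalue,
             stringsAsFactors = FALSE)
}
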