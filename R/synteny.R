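# Gene-order conservation: shared adjacent gene pairs between genomes.
#
# The statistic is the number of neighboring gene pairs common to two
# genomes' (circular) gene orders.  The published counts do not state a
# counting convention, so every switch is exposed in the policy object;
# the defaults (unordered pairs, strand-insensitive, wrap-around pair
# included, unnamed ORFs excluded, IR duplicates collapsed, all three
# feature types included) are the documented best reproduction.

#' Synteny counting policy
#'
#' @param types feature types to include (default CDS, tRNA, rRNA).
#' @param include_orfs keep unnamed ORFs (`orf<digits>`)? Default FALSE.
#' @param collapse_ir collapse IR-resident duplicate loci to one copy?
#'   Default TRUE (requires per-genome partitions, see
#'   [shared_adjacency()]).
#' @return a list of class `synteny_policy`.
#' @export
synteny_policy <- function(types = FEATURE_TYPES, include_orfs = FALSE,
                           collapse_ir = TRUE) {
  structure(list(types = types, include_orfs = include_orfs,
                 collapse_ir = collapse_ir), class = "synteny_policy")
}

#' Adjacent gene pairs of a genome
#'
#' Genes retained under `policy` are ordered by start coordinate around
#' the circle; for a circular genome with n retained genes exactly n
#' unordered adjacent pairs are returned (n - 1 for a linear genome).
#' Strand is ignored.  Genes nested within another gene are kept at the
#' position of their start coordinate.
#'
#' @param genome an [annotated_genome()].
#' @param policy a [synteny_policy()].
#' @param partition optional [partition_quadripartite()] result used for
#'   IR-duplicate collapsing.
#' @return character vector of canonical pair keys (`"a|b"`, names in
#'   lexicographic order); duplicates retained (multiset semantics).
#'   Empty when fewer than 2 genes are retained.
#' @export
adjacency_pairs <- function(genome, policy = synteny_policy(),
                            partition = NULL) {
  genes <- retained_gene_order(genome, policy, partition)
  n <- length(genes)
  if (n < 2L) return(character(0))
  nxt <- c(genes[-1L], if (genome$topology == "circular") genes[1L])
  cur <- genes[seq_along(nxt)]
  paste(pmin(cur, nxt), pmax(cur, nxt), sep = "|")
}

retained_gene_order <- function(genome, policy, partition = NULL) {
  feats <- genome$features
  if (!length(feats)) return(character(0))
  L <- genome_length(genome)
  keep <- vapply(feats, `[[`, "", "ftype") %in% policy$types
  if (!policy$include_orfs)
    keep <- keep & vapply(feats, `[[`, TRUE, "conserved")
  feats <- feats[keep]
  if (policy$collapse_ir && !is.null(partition)) {
    dup <- ir_duplicate_indices(feats, partition, L)
    if (length(dup)) feats <- feats[-dup]
  }
  starts <- vapply(feats, function(f) feature_span(f, L)$start, 0L)
  vapply(feats, `[[`, "", "name")[order(starts)]
}

#' Shared adjacent gene pairs between two genomes
#'
#' The multiset intersection of the two genomes' adjacency-pair sets.
#' Symmetric in its arguments.
#'
#' @param a,b [annotated_genome()] objects (names normalized with the same
#'   synonym table), or character vectors of pair keys as returned by
#'   [adjacency_pairs()].
#' @param policy a [synteny_policy()].
#' @param partition_a,partition_b optional quadripartite partitions for IR
#'   collapsing.
#' @return a list of class `synteny_result`: `shared_count`,
#'   `shared_pairs` (character vector), `n_a`, `n_b` (gene counts used).
#' @export
shared_adjacency <- function(a, b, policy = synteny_policy(),
                             partition_a = NULL, partition_b = NULL) {
  na <- if (is.character(a)) length(a)
        else length(retained_gene_order(a, policy, partition_a))
  nb <- if (is.character(b)) length(b)
        else length(retained_gene_order(b, policy, partition_b))
  pa <- if (is.character(a)) a else adjacency_pairs(a, policy, partition_a)
  pb <- if (is.character(b)) b else adjacency_pairs(b, policy, partition_b)
  ta <- table(pa); tb <- table(pb)
  common <- intersect(names(ta), names(tb))
  counts <- pmin(as.integer(ta[common]), as.integer(tb[common]))
  shared <- rep(common, counts)
  structure(list(shared_count = length(shared),
                 shared_pairs = sort(shared),
                 n_a = na, n_b = nb),
            class = "synteny_result")
}

#' @export
print.synteny_result <- function(x, ...) {
  cat(sprintf("shared adjacent gene pairs: %d (of %d / %d)\n",
              x$shared_count, x$n_a, x$n_b))
  invisible(x)
}
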