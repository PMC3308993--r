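# Relative node ages on ultrametric (relaxed-clock) trees.

#' Relative age ratio of two clades on an ultrametric tree
#'
#' On an ultrametric tree node heights are relative ages, so the ratio
#' `height(MRCA(clade_old)) / height(MRCA(clade_young))` measures how
#' much older one divergence is than another.  When per-node 95% height
#' intervals are available, the ratio interval
#' `[low_old / high_young, high_old / low_young]` is reported as well; it
#' always contains the point ratio.
#'
#' @param tree an [ape::phylo] object or path to a Newick file; must be
#'   ultrametric within relative tolerance `tol`.
#' @param clade_old,clade_young character vectors of tip labels; node ages
#'   are taken at each clade's MRCA.
#' @param intervals optional `data.frame` with columns `taxa`
#'   (comma-separated tip labels identifying a node by its MRCA), `low`,
#'   `high` - e.g. read with [read_node_intervals()].
#' @param tol relative tolerance for the ultrametricity check
#'   (default 1e-6).
#' @return list of class `age_ratio`: `ratio`, `age_old`, `age_young`,
#'   and `interval` (length-2 numeric or NULL).
#' @export
node_age_ratio <- function(tree, clade_old, clade_young, intervals = NULL,
                           tol = 1e-6) {
  if (is.character(tree) && length(tree) == 1L) tree <- ape::read.tree(tree)
  if (!inherits(tree, "phylo")) pc_stop("tree must be a phylo object")
  depths <- ape::node.depth.edgelength(tree)
  ntip <- length(tree$tip.label)
  tip_depths <- depths[seq_len(ntip)]
  span <- max(tip_depths)
  if (span <= 0) pc_stop("tree has zero depth")
  if ((max(tip_depths) - min(tip_depths)) / span > tol)
    pc_stop("tree is not ultrametric within relative tolerance ", tol)
  heights <- span - depths

  node_of <- function(tips) {
    miss <- setdiff(tips, tree$tip.label)
    if (length(miss))
      pc_stop("tip label(s) not in tree: ", paste(miss, collapse = ", "))
    if (length(tips) == 1L) which(tree$tip.label == tips)
    else ape::getMRCA(tree, tips)
  }
  n_old <- node_of(clade_old); n_young <- node_of(clade_young)
  h_old <- heights[n_old]; h_young <- heights[n_young]
  if (h_young <= span * tol)
    pc_stop("young clade has (near-)zero node height; ratio undefined")
  out <- list(ratio = h_old / h_young, age_old = h_old, age_young = h_young,
              interval = NULL)
  if (!is.null(intervals)) {
    iv_old <- lookup_interval(tree, intervals, n_old)
    iv_young <- lookup_interval(tree, intervals, n_young)
    if (!is.null(iv_old) && !is.null(iv_young)) {
      if (iv_young[1L] <= 0) pc_stop("young node interval reaches zero age")
      out$interval <- c(iv_old[1L] / iv_young[2L], iv_old[2L] / iv_young[1L])
    }
  }
  structure(out, class = "age_ratio")
}

lookup_interval <- function(tree, intervals, node) {
  if (!all(c("taxa", "low", "high") %in% names(intervals)))
    pc_stop("intervals needs columns taxa, low, high")
  for (i in seq_len(nrow(intervals))) {
    tips <- trimws(strsplit(intervals$taxa[i], ",")[[1L]])
    if (!all(tips %in% tree$tip.label)) next
    n <- if (length(tips) == 1L) which(tree$tip.label == tips)
         else ape::getMRCA(tree, tips)
    if (identical(n, node))
      return(c(intervals$low[i], intervals$high[i]))
  }
  NULL
}

#' Read a node-interval sidecar table
#'
#' TSV with columns `taxa` (comma-separated tip labels whose MRCA is the
#' node), `low`, `high` (95% interval bounds on relative node height).
#'
#' @param path TSV path.
#' @return `data.frame` with those columns.
#' @export
read_node_intervals <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           comment.char = "#")
  if (!all(c("taxa", "low", "high") %in% names(tab)))
    pc_stop("expected columns taxa, low, high in ", path)
  tab
}

#' @export
print.age_ratio <- function(x, ...) {
  cat(sprintf("relative node-age ratio: %.3f (old %.4g / young %.4g)\n",
              x$ratio, x$age_old, x$age_young))
  if (!is.null(x$interval))
    cat(sprintf("  95%% interval ratio: [%.3f, %.3f]\n",
                x$interval[1L], x$interval[2L]))
  invisible(x)
}
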