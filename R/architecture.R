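# Genome architecture: inverted repeats, quadripartite partition,
# coding-strand switch points, tandem repeats.

#' Detect inverted repeats
#'
#' Seed-and-extend search for inverted repeats: exact k-mer matches
#' between the sequence and its reverse complement are grouped by
#' anti-diagonal (indel-free inverted matches stay on one diagonal),
#' extended outwards base by base while the cumulative mismatch rate stays
#' within `max_mismatch_rate`, and finally trimmed to the maximal-scoring
#' sub-window (match +1, mismatch -3, ties resolved towards the longer
#' window) so that hits end on matching bases and random flanking sequence
#' is not absorbed.  Overlapping hits are collapsed, keeping the longest.
#' Hits are reported sorted by length descending, ties by smaller start.
#'
#' Hits whose two copies would cross the circular origin are not searched
#' for; place the origin in a single-copy region (as genome numbering
#' conventions do) before calling.
#'
#' @param genome an [annotated_genome()] or a nucleotide string.
#' @param min_len minimum repeat length to report (default 1000).
#' @param max_mismatch_rate maximum fraction of substitutions within a hit
#'   (default 0.01; indels are not modelled).
#' @param k seed k-mer size (default 21).
#' @return a `data.frame` with columns `start_a`, `end_a`, `start_b`,
#'   `end_b` (0-based half-open), `length`, `mismatches`; zero rows when
#'   nothing is found (including `min_len` > genome size).
#' @export
detect_inverted_repeats <- function(genome, min_len = 1000,
                                    max_mismatch_rate = 0.01, k = 21L) {
  seq <- if (inherits(genome, "annotated_genome")) genome$sequence
         else toupper(genome)
  L <- nchar(seq)
  empty <- data.frame(start_a = integer(0), end_a = integer(0),
                      start_b = integer(0), end_b = integer(0),
                      length = integer(0), mismatches = integer(0))
  if (min_len > L || L < 2L * k) return(empty)

  rseq <- reverse_complement(seq)
  s <- strsplit(seq, "")[[1L]]
  r <- strsplit(rseq, "")[[1L]]

  # Seed stage: anchor k-mers taken every `step` bases of the forward
  # sequence are matched exactly against the reverse complement (C-level
  # via matchPDict).  A repeat is seeded whenever it contains a clean
  # window of k + step - 1 bases, which sparse substitutions allow.
  np <- L - k + 1L
  step <- max(1L, k %/% 3L)
  anchor <- seq.int(1L, np, by = step)
  kms <- substring(seq, anchor, anchor + k - 1L)
  ok <- !grepl("[^ACGT]", kms)
  anchor <- anchor[ok]; kms <- kms[ok]
  if (!length(anchor)) return(empty)
  uk <- unique(kms)
  pd <- Biostrings::PDict(uk)
  mt <- Biostrings::matchPDict(pd, Biostrings::DNAString(rseq))
  js_per_unique <- Biostrings::startIndex(mt)
  js_per_anchor <- js_per_unique[match(kms, uk)]
  nj <- lengths(js_per_anchor)
  keep <- nj > 0L & nj <= 10L           # skip hyper-repetitive seeds
  if (!any(keep)) return(empty)
  pairs_i <- rep(anchor[keep], nj[keep])
  pairs_j <- unlist(js_per_anchor[keep])

  # diagonal d = i - j is invariant along an indel-free inverted match
  d <- pairs_i - pairs_j

  hits <- list()
  for (dg in unique(d)) {
    sel <- d == dg
    i0 <- min(pairs_i[sel]); i1 <- max(pairs_i[sel]) + k - 1L
    ext <- extend_diagonal(s, r, i0, i1, dg, L, max_mismatch_rate)
    if (is.null(ext)) next
    hits[[length(hits) + 1L]] <- ext
  }
  if (!length(hits)) return(empty)
  tab <- do.call(rbind, hits)

  # intervals in s-coordinates; A = copy with smaller start
  a_start <- tab[, "i0"] - 1L           # 0-based
  a_end <- tab[, "i1"]
  b_start <- L - (tab[, "i1"] - tab[, "d"])   # r pos j1 -> s start
  b_end <- L - (tab[, "i0"] - tab[, "d"]) + 1L
  swap <- b_start < a_start
  tmp_s <- a_start[swap]; tmp_e <- a_end[swap]
  a_start[swap] <- b_start[swap]; a_end[swap] <- b_end[swap]
  b_start[swap] <- tmp_s; b_end[swap] <- tmp_e

  res <- data.frame(start_a = a_start, end_a = a_end,
                    start_b = b_start, end_b = b_end,
                    length = tab[, "len"], mismatches = tab[, "mm"])
  res <- res[res$length >= min_len & res$start_b >= res$end_a, , drop = FALSE]
  res <- unique(res)
  if (!nrow(res)) return(empty)
  res <- res[order(-res$length, res$start_a), , drop = FALSE]

  # drop hits overlapping an already-kept (longer) hit
  keep <- logical(nrow(res))
  for (i in seq_len(nrow(res))) {
    ok <- TRUE
    for (j in which(keep)) {
      if (ranges_overlap(res[i, ], res[j, ])) { ok <- FALSE; break }
    }
    keep[i] <- ok
  }
  res <- res[keep, , drop = FALSE]
  rownames(res) <- NULL
  res
}

ranges_overlap <- function(x, y) {
  ov <- function(s1, e1, s2, e2) s1 < e2 && s2 < e1
  ov(x$start_a, x$end_a, y$start_a, y$end_a) ||
    ov(x$start_a, x$end_a, y$start_b, y$end_b) ||
    ov(x$start_b, x$end_b, y$start_a, y$end_a) ||
    ov(x$start_b, x$end_b, y$start_b, y$end_b)
}

# Extend a seed run [i0, i1] (1-based, inclusive, in s) on diagonal d,
# where s[i] pairs with r[i - d].  Returns c(i0, i1, d, len, mm) after
# score trimming, or NULL.
extend_diagonal <- function(s, r, i0, i1, d, L, rate) {
  lo_lim <- max(1L, 1L + d)            # need i - d >= 1
  hi_lim <- min(L, L + d)              # need i - d <= L
  # avoid self-overlap of the two copies: s interval [i0, i1] vs
  # [L - (i1 - d) + 1, L - (i0 - d) + 1]; stop extension at the midpoint
  # of the palindrome centre when the copies would collide.
  m <- s[lo_lim:hi_lim] == r[(lo_lim:hi_lim) - d]
  offs <- i0 - lo_lim                   # index of i0 within m is offs + 1

  idx0 <- offs + 1L
  idx1 <- i1 - lo_lim + 1L
  n <- length(m)
  # alternate greedy rate-bounded extension with score trimming until the
  # window is stable: trimming random flanking sequence returns mismatch
  # budget so extension can resume on the other side
  for (round in 1:20) {
    prev <- c(idx0, idx1)
    ext1 <- extend_window(m, idx0, idx1, rate)
    idx0 <- ext1[1L]; idx1 <- ext1[2L]
    sc <- ifelse(m[idx0:idx1], 1L, -3L)
    best <- best_window(cumsum(sc))
    if (is.null(best)) return(NULL)
    idx1 <- idx0 + best[2L] - 1L
    idx0 <- idx0 + best[1L] - 1L
    if (identical(prev, c(idx0, idx1))) break
  }
  mm <- sum(!m[idx0:idx1])
  i0 <- idx0 + lo_lim - 1L
  i1 <- idx1 + lo_lim - 1L
  c(i0 = i0, i1 = i1, d = d, len = i1 - i0 + 1L, mm = mm)
}

# Greedy rate-bounded outward extension of window [idx0, idx1] on match
# vector m: repeatedly jump to the next matching position on either side
# while the cumulative mismatch rate stays within `rate`.
extend_window <- function(m, idx0, idx1, rate) {
  n <- length(m)
  mm <- sum(!m[idx0:idx1])
  len <- idx1 - idx0 + 1L
  repeat {
    ext <- FALSE
    if (idx0 > 1L) {
      nxt <- idx0 - 1L
      while (nxt >= 1L && !m[nxt]) nxt <- nxt - 1L
      if (nxt >= 1L) {
        add_mm <- sum(!m[nxt:(idx0 - 1L)])
        if ((mm + add_mm) / (len + (idx0 - nxt)) <= rate) {
          mm <- mm + add_mm; len <- len + (idx0 - nxt); idx0 <- nxt
          ext <- TRUE
        }
      }
    }
    if (idx1 < n) {
      nxt <- idx1 + 1L
      while (nxt <= n && !m[nxt]) nxt <- nxt + 1L
      if (nxt <= n) {
        add_mm <- sum(!m[(idx1 + 1L):nxt])
        if ((mm + add_mm) / (len + (nxt - idx1)) <= rate) {
          mm <- mm + add_mm; len <- len + (nxt - idx1); idx1 <- nxt
          ext <- TRUE
        }
      }
    }
    if (!ext) break
  }
  c(idx0, idx1)
}

# Maximal-sum window of a cumulative-sum vector; ties -> longer window,
# then smaller start.  Returns c(from, to) in 1-based indices.
best_window <- function(cs) {
  n <- length(cs)
  cs0 <- c(0L, cs)
  best_sum <- -Inf; best <- NULL
  min_val <- 0L; min_idx <- 0L
  for (t in seq_len(n)) {
    val <- cs0[t + 1L] - min_val
    if (val > best_sum ||
        (val == best_sum && !is.null(best) &&
         (t - min_idx) > (best[2L] - best[1L] + 1L))) {
      best_sum <- val
      best <- c(min_idx + 1L, t)
    }
    if (cs0[t + 1L] < min_val) { min_val <- cs0[t + 1L]; min_idx <- t }
  }
  if (is.null(best) || best_sum <= 0L) return(NULL)
  best
}

#' Partition a circular genome into LSC / SSC / IR regions
#'
#' Given the top inverted-repeat hit, the two arcs between the repeat
#' copies become the single-copy regions: the shorter remaining arc is the
#' SSC, the longer the LSC.  Gene blocks that sit immediately adjacent to
#' one IR copy and are set off from the rest of the arc by a spacer longer
#' than `max_gap` are reported as `insertions` (single-copy blocks
#' inserted into/next to one repeat copy) and excluded from LSC/SSC.  The
#' reported intervals tile the circle exactly.
#'
#' @param genome an [annotated_genome()]; must be circular.
#' @param hit one row of [detect_inverted_repeats()] output (the top hit
#'   by default ordering).
#' @param max_gap maximum intergenic gap (bases) within an insertion block
#'   and between the block and the IR boundary (default 150).
#' @return a list of class `quadripartite_partition` with elements `ira`,
#'   `irb`, `lsc`, `ssc` ([pc_interval()]), `insertions` (list of
#'   intervals), and `degenerate` (TRUE when one arc has length 0).
#' @export
partition_quadripartite <- function(genome, hit, max_gap = 150L) {
  if (genome$topology != "circular")
    pc_stop("quadripartite partition is defined on circular genomes only")
  L <- genome_length(genome)
  ira <- pc_interval(hit$start_a, hit$end_a)
  irb <- pc_interval(hit$start_b, hit$end_b)

  arc <- function(from, to) {           # half-open arc on the circle
    if (from == to %% L) return(NULL)   # zero-length arc
    if (to > from) pc_interval(from, to) else pc_interval(from, to %% L,
                                                          wraps = to %% L <= from)
  }
  arc1 <- arc(ira$end %% L, irb$start)
  arc2 <- arc(irb$end %% L, ira$start)
  degenerate <- is.null(arc1) || is.null(arc2)

  # carve insertion blocks off the arc ends that abut an IR copy
  insertions <- list()
  carve <- function(a) {
    if (is.null(a)) return(NULL)
    for (side in c("left", "right")) {
      blk <- insertion_block(genome, a, side, max_gap, L)
      if (!is.null(blk)) {
        insertions[[length(insertions) + 1L]] <<- blk$insertion
        a <- blk$rest
        if (is.null(a)) break
      }
    }
    a
  }
  arc1 <- carve(arc1); arc2 <- carve(arc2)

  len1 <- if (is.null(arc1)) 0L else iv_length(arc1, L)
  len2 <- if (is.null(arc2)) 0L else iv_length(arc2, L)
  if (len1 <= len2) { ssc <- arc1; lsc <- arc2 } else { ssc <- arc2; lsc <- arc1 }

  structure(list(ira = ira, irb = irb, lsc = lsc, ssc = ssc,
                 insertions = insertions, degenerate = degenerate),
            class = "quadripartite_partition")
}

# Find a gene block at the `side` end of arc `a` that is separated from
# the remainder of the arc by a gap > max_gap.  Returns NULL or
# list(insertion = interval, rest = remaining arc interval or NULL).
insertion_block <- function(genome, a, side, max_gap, L) {
  alen <- iv_length(a, L)
  feats <- genome$features
  if (!length(feats)) return(NULL)
  spans <- lapply(feats, feature_span, L = L)
  inside <- vapply(spans, function(sp) iv_contains(a, sp, L), TRUE)
  if (!any(inside)) return(NULL)
  sp <- spans[inside]
  # offsets of each contained feature from the arc start
  off <- vapply(sp, function(x) (x$start - a$start) %% L, 0)
  lens <- vapply(sp, iv_length, 0L, genome_length = L)
  ord <- order(off)
  off <- off[ord]; lens <- lens[ord]
  ends <- off + lens
  n <- length(off)
  if (side == "left") {
    if (off[1L] > max_gap) return(NULL)
    stop_at <- 0L
    for (t in seq_len(n)) {
      nxt_gap <- if (t < n) off[t + 1L] - ends[t] else alen - ends[t]
      if (nxt_gap > max_gap) { stop_at <- t; break }
    }
    if (stop_at == 0L || stop_at == n) return(NULL)  # absorbs whole arc
    cut <- ends[stop_at]                 # insertion = [0, cut) of the arc
    ins <- shift_iv(a$start, 0L, cut, L)
    rest <- shift_iv(a$start, cut, alen, L)
    list(insertion = ins, rest = rest)
  } else {
    if (alen - ends[n] > max_gap) return(NULL)
    stop_at <- 0L
    for (t in rev(seq_len(n))) {
      prv_gap <- if (t > 1L) off[t] - ends[t - 1L] else off[t]
      if (prv_gap > max_gap) { stop_at <- t; break }
    }
    if (stop_at <= 1L) return(NULL)      # no break, or absorbs whole arc
    cut <- off[stop_at]
    ins <- shift_iv(a$start, cut, alen, L)
    rest <- shift_iv(a$start, 0L, cut, L)
    list(insertion = ins, rest = rest)
  }
}

# Interval [from, to) expressed as offsets from `origin` on a circle.
shift_iv <- function(origin, from, to, L) {
  s <- (origin + from) %% L
  e <- (origin + to) %% L
  if (to == from) return(NULL)
  pc_interval(s, if (e == 0L) L else e, wraps = e <= s && e != 0L)
}

#' Detect the coding-strand switch points of a circular genome
#'
#' Plastid genomes commonly show a two-arc strand layout: most genes on
#' one arc are coded by the plus strand and most genes on the other arc by
#' the minus strand.  This function exhaustively searches all ordered
#' pairs of inter-gene boundaries for the two-arc partition maximizing the
#' number of genes lying on their arc's majority strand.
#'
#' @param genome an [annotated_genome()] with at least 2 features.
#' @return a list of class `strand_layout`: `switch_points` (genomic
#'   positions between adjacent genes; empty when all genes share one
#'   strand), `boundaries` (indices into the start-sorted gene order:
#'   the arc runs from gene `b1+1` to gene `b2`), and `consistency`
#'   (fraction of genes on their arc's majority strand).
#' @export
detect_strand_switch <- function(genome) {
  feats <- genome$features
  if (length(feats) < 2L) pc_stop("need at least 2 features")
  L <- genome_length(genome)
  spans <- lapply(feats, feature_span, L = L)
  ord <- order(vapply(spans, `[[`, 0L, "start"))
  feats <- feats[ord]; spans <- spans[ord]
  strands <- vapply(feats, `[[`, "", "strand")
  n <- length(strands)
  plus <- as.integer(strands == "+")
  if (all(plus == 1L) || all(plus == 0L))
    return(structure(list(switch_points = numeric(0),
                          boundaries = integer(0), consistency = 1),
                     class = "strand_layout"))

  cp <- cumsum(plus)
  total_p <- cp[n]
  best <- -1L; best_b <- c(0L, 0L)
  for (b1 in 0L:(n - 1L)) {
    for (b2 in (b1 + 1L):n) {
      inside_n <- b2 - b1
      inside_p <- cp[b2] - if (b1 > 0L) cp[b1] else 0L
      out_n <- n - inside_n
      out_p <- total_p - inside_p
      score <- max(inside_p, inside_n - inside_p) + max(out_p, out_n - out_p)
      if (score > best) { best <- score; best_b <- c(b1, b2) }
    }
  }
  # boundary after gene i sits between span end of gene i and span start
  # of gene i+1 (midpoint of the intergenic gap, on the circle)
  boundary_pos <- function(i) {         # i in 0..n-1; boundary after gene i
    prev <- if (i == 0L) n else i
    e <- spans[[prev]]$end %% L
    s <- spans[[(i %% n) + 1L]]$start
    gap <- (s - e) %% L
    (e + gap %/% 2L) %% L
  }
  structure(list(
    switch_points = c(boundary_pos(best_b[1L]), boundary_pos(best_b[2L] %% n)),
    boundaries = best_b,
    consistency = best / n
  ), class = "strand_layout")
}

#' Find tandem repeats
#'
#' For each period p, maximal runs of positions i with `seq[i] ==
#' seq[i + p]` are located; a run of length r plus the final period spans
#' `r + p` bases and corresponds to `(r + p) / p` copies.  Runs reaching
#' `min_copies` are reported with a majority-vote consensus unit.  A run
#' whose consensus unit is itself perfectly periodic with a shorter period
#' (e.g. a homopolymer scanned at p = 5, or a dimer repeat scanned at
#' twice its true period) is suppressed, so each locus is reported at its
#' primitive period only.
#'
#' @param seq nucleotide string (or an [annotated_genome()]).
#' @param min_period minimum period in bases (default 5).
#' @param max_period maximum period in bases (default 100).
#' @param min_copies minimum copy number, may be fractional (default 2.5).
#' @return `data.frame` with columns `start` (0-based), `period`, `copies`
#'   (exact; round to 1 decimal for reporting), `span`, `unit`.
#' @export
find_tandem_repeats <- function(seq, min_period = 5L, max_period = 100L,
                                min_copies = 2.5) {
  if (inherits(seq, "annotated_genome")) seq <- seq$sequence
  seq <- toupper(seq)
  s <- strsplit(seq, "")[[1L]]
  L <- length(s)
  out <- list()
  for (p in seq.int(min_period, min(max_period, max(1L, L - 1L)))) {
    if (L <= p) break
    m <- s[seq_len(L - p)] == s[(p + 1L):L]
    r <- rle(m)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    runs <- which(r$values & (r$lengths + p) / p >= min_copies)
    for (ri in runs) {
      i <- starts[ri]; run <- r$lengths[ri]
      span <- run + p
      unit <- consensus_unit(s, i, p, span)
      if (primitive_period(unit) < p) next
      out[[length(out) + 1L]] <- data.frame(
        start = i - 1L, period = p, copies = span / p, span = span,
        unit = unit, stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(start = integer(0), period = integer(0),
                      copies = numeric(0), span = integer(0),
                      unit = character(0)))
  res <- do.call(rbind, out)
  res <- res[order(res$start, res$period), , drop = FALSE]
  rownames(res) <- NULL
  res
}

consensus_unit <- function(s, i, p, span) {
  ncopy <- span %/% p
  mat <- matrix(s[i:(i + ncopy * p - 1L)], nrow = p)
  paste(apply(mat, 1L, function(col)
    names(sort(table(col), decreasing = TRUE))[1L]), collapse = "")
}

primitive_period <- function(unit) {
  u <- strsplit(unit, "")[[1L]]
  p <- length(u)
  for (q in seq_len(p - 1L)) {
    if (p %% q == 0L && all(u == u[((seq_len(p) - 1L) %% q) + 1L]))
      return(q)
  }
  p
}
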