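# Synthetic plastid genome generator with full ground truth.
#
# The generator emulates the organization of a quadripartite euglenid-like
# plastid chromosome: a circular molecule with a large and a small
# single-copy region, two near-identical inverted repeats carrying the
# rRNA operon remnant (16S + 23S) and a non-coding spacer with planted
# tandem repeats, optional single-copy gene blocks inserted next to one
# repeat copy, a two-arc coding-strand layout with a switch point planted
# in the gene order, a minority of intron-containing CDS, and i.i.d.
# background sequence at a configurable GC.  Every planted quantity is
# returned as ground truth so analysis stages can be tested against it.

#' Simulation configuration
#'
#' Defaults emulate the published euglenid plastid regime: ~60 kb circle,
#' GC 0.34, IR of 6000 bp with 3 substitutions between the copies (all in
#' the 23S gene), an 8-gene block inserted next to one IR copy and a
#' single tRNA next to the other, an SSC of ~1 kb holding one unnamed
#' ORF, two intron-containing CDS, two tandem repeats (3 x 11 bp and
#' 3.4 x 33 bp) in the IR spacer, and a strand switch at 2/3 of the gene
#' order.
#'
#' @param genome_size circle size in bases.
#' @param gc background GC fraction.
#' @param n_cds named single-copy CDS in the LSC.
#' @param n_orf unnamed ORFs (`orf<digits>`) in the LSC, additional CDS.
#' @param n_trna tRNAs in the LSC (distinct species).
#' @param n_introns how many LSC CDS carry one intron each.
#' @param cds_len_range CDS exon length range (rounded to codons).
#' @param intron_len_range intron length range.
#' @param trna_len tRNA gene length.
#' @param ir_length inverted repeat length (bases per copy).
#' @param ir_mismatches substitutions between the IR copies.
#' @param rrn16_len,rrn23_len rRNA gene lengths inside the IR.
#' @param vntr data.frame with columns `period`, `copies` for tandem
#'   repeats planted in the IR spacer.
#' @param ins_a_cds,ins_a_trna genes in the insertion block adjacent to
#'   IRA (one CDS of the block is an unnamed ORF when `ins_a_cds` > 0).
#' @param ins_b_trna tRNAs in the insertion block adjacent to IRB.
#' @param ssc_orf_len length of the unnamed ORF occupying the SSC.
#' @param switch_frac planted strand-switch position as a fraction of the
#'   gene order (must fall among the LSC genes).
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(genome_size = 60000L, gc = 0.34,
                       n_cds = 40L, n_orf = 2L, n_trna = 17L,
                       n_introns = 2L,
                       cds_len_range = c(300L, 1200L),
                       intron_len_range = c(150L, 1500L),
                       trna_len = 72L,
                       ir_length = 6000L, ir_mismatches = 3L,
                       rrn16_len = 1400L, rrn23_len = 2900L,
                       vntr = data.frame(period = c(11L, 33L),
                                         copies = c(3, 3.4)),
                       ins_a_cds = 6L, ins_a_trna = 2L, ins_b_trna = 1L,
                       ssc_orf_len = 654L,
                       switch_frac = 2 / 3) {
  cfg <- as.list(environment())
  if (rrn16_len + rrn23_len + 300L > ir_length)
    pc_stop("ir_length too small for the rRNA genes plus spacer")
  structure(cfg, class = "sim_config")
}

# fixed layout gaps (bases)
GAP_MIN <- 30L        # minimum intergenic gap
GAP_EDGE <- 30L       # IR edge -> first insertion-block gene
GAP_BLOCK <- 30L      # between insertion-block genes
GAP_SEP <- 400L       # separator ending an insertion block
GAP_SSC_TAIL <- 151L  # SSC tail gap (just above the carving threshold)

random_dna <- function(n, gc) {
  if (n <= 0L) return(character(0))
  sample(c("A", "T", "G", "C"), n, replace = TRUE,
         prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2))
}

# random ORF: ATG + sense codons + stop, total length `len` (multiple of 3)
random_orf <- function(len, gc) {
  stopifnot(len %% 3L == 0L, len >= 9L)
  ncod <- len %/% 3L - 2L
  stops <- c("TAA", "TAG", "TGA")
  codons <- character(0)
  while (length(codons) < ncod) {
    draw <- matrix(random_dna(3L * (ncod - length(codons) + 8L), gc),
                   nrow = 3L)
    cand <- paste0(draw[1L, ], draw[2L, ], draw[3L, ])
    codons <- c(codons, cand[!cand %in% stops])
  }
  paste0("ATG", paste(codons[seq_len(ncod)], collapse = ""), "TAA")
}

# tandem-repeat unit with primitive period == period
random_unit <- function(period, gc) {
  repeat {
    u <- paste(random_dna(period, gc), collapse = "")
    if (primitive_period(u) == period) return(u)
  }
}

#' Simulate an annotated plastid-like genome with known ground truth
#'
#' See [sim_config()] for the planted structure.  Deterministic per
#' `(config, seed)`: the same pair regenerates a byte-identical genome.
#'
#' @param config a [sim_config()].
#' @param seed integer random seed.
#' @return list with elements `genome` (an [annotated_genome()]) and
#'   `truth` (a list of every planted parameter: IR intervals/mismatches,
#'   insertion intervals, strand-switch layout, tandem repeats, per-gene
#'   table, and the expected feature-summary row).
#' @export
simulate_genome <- function(config = sim_config(), seed = 1L) {
  set.seed(seed)
  L <- as.integer(config$genome_size)
  gc <- config$gc

  # ---- plan gene complements ------------------------------------------
  rng_len <- function(lo, hi) {
    len <- sample(seq.int(lo, hi), 1L)
    (len %/% 3L) * 3L
  }
  aa <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K",
          "M", "F", "P", "S", "T", "W", "Y", "V")
  anticodons <- apply(expand.grid(c("A", "C", "G", "U"),
                                  c("A", "C", "G", "U"),
                                  c("A", "C", "G", "U")), 1L, paste,
                      collapse = "")
  n_trna_total <- config$n_trna + config$ins_a_trna + config$ins_b_trna
  trna_names <- paste0("trn", rep(aa, length.out = n_trna_total), "-",
                       sample(anticodons, n_trna_total))
  cds_pool <- paste0(
    rep(c("psa", "psb", "pet", "atp", "rps", "rpl", "rpo", "ycf"), each = 12L),
    rep(1:12, times = 8L))
  named_cds <- sample(cds_pool, config$n_cds + config$ins_a_cds - 1L)
  orf_names <- paste0("orf", sample(100:999, config$n_orf + 2L))

  # gene plan rows: name, ftype, region, length (exon), intron length
  plan <- list()
  add <- function(name, ftype, region, len, intron = 0L)
    plan[[length(plan) + 1L]] <<- list(name = name, ftype = ftype,
                                       region = region, len = as.integer(len),
                                       intron = as.integer(intron))
  # LSC: interleave tRNAs among CDS deterministically
  lsc_cds <- c(named_cds[seq_len(config$n_cds)],
               orf_names[seq_len(config$n_orf)])
  lsc_cds <- sample(lsc_cds)
  intron_in <- sample(seq_len(config$n_cds), config$n_introns)
  intron_len <- vapply(seq_len(config$n_introns), function(i)
    rng_len(config$intron_len_range[1L], config$intron_len_range[2L]), 0L)
  it <- 0L
  trna_slots <- sort(sample(seq_along(lsc_cds), config$n_trna, replace = TRUE))
  ti <- 0L
  for (ci in seq_along(lsc_cds)) {
    nm <- lsc_cds[ci]
    is_named <- !grepl("^orf", nm)
    intr <- 0L
    if (is_named && match(nm, named_cds) %in% intron_in) {
      it <- it + 1L
      intr <- intron_len[min(it, length(intron_len))]
    }
    add(nm, "CDS", "lsc",
        rng_len(config$cds_len_range[1L], config$cds_len_range[2L]), intr)
    while (ti < config$n_trna && trna_slots[ti + 1L] == ci) {
      ti <- ti + 1L
      add(trna_names[ti], "tRNA", "lsc", config$trna_len)
    }
  }
  while (ti < config$n_trna) {
    ti <- ti + 1L
    add(trna_names[ti], "tRNA", "lsc", config$trna_len)
  }
  # insertion blocks
  if (config$ins_a_trna > 0L)
    for (i in seq_len(config$ins_a_trna))
      add(trna_names[config$n_trna + i], "tRNA", "ins_a", config$trna_len)
  if (config$ins_a_cds > 0L) {
    ins_named <- named_cds[config$n_cds + seq_len(config$ins_a_cds - 1L)]
    for (nm in ins_named) add(nm, "CDS", "ins_a", rng_len(300L, 600L))
    add(orf_names[config$n_orf + 1L], "CDS", "ins_a", rng_len(300L, 600L))
  }
  add(orf_names[config$n_orf + 2L], "CDS", "ssc", config$ssc_orf_len)
  if (config$ins_b_trna > 0L)
    for (i in seq_len(config$ins_b_trna))
      add(trna_names[config$n_trna + config$ins_a_trna + i], "tRNA",
          "ins_b", config$trna_len)

  plan_region <- vapply(plan, `[[`, "", "region")

  # ---- compute layout --------------------------------------------------
  span_of <- function(p) p$len + p$intron
  lsc_idx <- which(plan_region == "lsc")
  insa_idx <- which(plan_region == "ins_a")
  ssc_idx <- which(plan_region == "ssc")
  insb_idx <- which(plan_region == "ins_b")

  lsc_bases <- sum(vapply(plan[lsc_idx], span_of, 0L))
  insa_bases <- sum(vapply(plan[insa_idx], span_of, 0L))
  insb_bases <- sum(vapply(plan[insb_idx], span_of, 0L))
  ssc_bases <- sum(vapply(plan[ssc_idx], span_of, 0L))

  n_lsc_gaps <- length(lsc_idx) + 1L
  fixed <- lsc_bases + GAP_SEP +                       # LSC + pre-IRA gap
    2L * config$ir_length +
    (if (length(insa_idx)) GAP_EDGE + insa_bases +
       GAP_BLOCK * (length(insa_idx) - 1L) else 0L) +
    GAP_SEP + ssc_bases + GAP_SSC_TAIL +
    (if (length(insb_idx)) GAP_EDGE + insb_bases +
       GAP_BLOCK * (length(insb_idx) - 1L) else 0L) +
    GAP_SEP
  slack <- L - fixed - GAP_MIN * n_lsc_gaps
  if (slack < 0L)
    pc_stop("infeasible packing: planted genes need ", fixed +
              GAP_MIN * n_lsc_gaps, " bases but genome_size is ", L)
  extra <- stats::rmultinom(1L, slack, rep(1, n_lsc_gaps))[, 1L]
  lsc_gaps <- GAP_MIN + extra

  # walk the circle laying genes down
  chars <- random_dna(L, gc)
  feats <- list()
  genes_tab <- list()
  place_gene <- function(p, start0, strand) {
    sq <- switch(p$ftype,
                 CDS = random_orf(p$len, gc),
                 paste(random_dna(p$len, gc), collapse = ""))
    if (p$intron > 0L) {
      exon1 <- (p$len %/% 2L %/% 3L) * 3L
      intron_seq <- paste(random_dna(p$intron, gc), collapse = "")
      full <- paste0(substr(sq, 1L, exon1), intron_seq,
                     substr(sq, exon1 + 1L, p$len))
      segs <- list(pc_interval(start0, start0 + exon1),
                   pc_interval(start0 + exon1 + p$intron, start0 + p$len +
                                 p$intron))
    } else {
      full <- sq
      segs <- list(pc_interval(start0, start0 + p$len))
    }
    if (strand == "-") {
      full <- reverse_complement(full)
      segs <- rev(segs)
    }
    chars[(start0 + 1L):(start0 + nchar(full))] <<- strsplit(full, "")[[1L]]
    feats[[length(feats) + 1L]] <<-
      gene_feature(p$name, p$ftype, strand, segs)
    genes_tab[[length(genes_tab) + 1L]] <<-
      data.frame(name = feats[[length(feats)]]$name, raw_name = p$name,
                 ftype = p$ftype, strand = strand, start = start0,
                 end = start0 + p$len + p$intron, exon_bases = p$len,
                 intron_bases = p$intron, region = p$region,
                 stringsAsFactors = FALSE)
    start0 + p$len + p$intron
  }

  # strand plan: gene-order switch among LSC genes at switch_frac of the
  # total order; the second switch sits in the SSC tail (between the SSC
  # gene(s) and IRB), so each IR copy lies in a different arc.
  n_genes_total <- length(plan) + 4L          # + 2 rRNAs per IR copy
  k_switch <- floor(config$switch_frac * n_genes_total)
  if (k_switch < 1L || k_switch > length(lsc_idx))
    pc_stop("switch_frac places the strand switch outside the LSC gene run")
  strand_of <- function(order_idx, region) {
    switch(region,
           lsc = if (order_idx <= k_switch) "+" else "-",
           ins_a = "-", ssc = "-", ins_b = "+",
           pc_stop("bad region"))
  }

  pos <- 0L
  order_idx <- 0L
  for (j in seq_along(lsc_idx)) {
    pos <- pos + lsc_gaps[j]
    order_idx <- order_idx + 1L
    pos <- place_gene(plan[[lsc_idx[j]]], pos,
                      strand_of(order_idx, "lsc"))
  }
  pos <- pos + lsc_gaps[n_lsc_gaps] + GAP_SEP

  # ---- IRA -------------------------------------------------------------
  ira_start <- pos
  irlen <- config$ir_length
  ira <- random_dna(irlen, gc)
  # rRNA genes at the start of the repeat (IRA copy on the minus arc)
  r16 <- paste(random_dna(config$rrn16_len, gc), collapse = "")
  gap_r <- 60L
  r23_off <- config$rrn16_len + gap_r
  r23 <- paste(random_dna(config$rrn23_len, gc), collapse = "")
  ira[seq_len(config$rrn16_len)] <- strsplit(r16, "")[[1L]]
  ira[r23_off + seq_len(config$rrn23_len)] <- strsplit(r23, "")[[1L]]
  # spacer tandem repeats
  spacer0 <- r23_off + config$rrn23_len + 100L
  vntr_truth <- list()
  vpos <- spacer0
  for (vi in seq_len(nrow(config$vntr))) {
    p <- config$vntr$period[vi]
    span <- round(p * config$vntr$copies[vi])
    if (vpos + span + 1L > irlen)
      pc_stop("ir_length too small for the configured VNTRs")
    unit <- random_unit(p, gc)
    reps <- strsplit(strrep(unit, ceiling(span / p)), "")[[1L]][seq_len(span)]
    ira[vpos + seq_len(span)] <- reps
    # break the periodicity immediately before and after the array
    u <- strsplit(unit, "")[[1L]]
    ira[vpos] <- setdiff(c("A", "C", "G", "T"), u[p])[1L]
    ira[vpos + span + 1L] <-
      setdiff(c("A", "C", "G", "T"), u[(span %% p) + 1L])[1L]
    vntr_truth[[vi]] <- data.frame(start = ira_start + vpos, period = p,
                                   copies = span / p, span = span,
                                   unit = unit, stringsAsFactors = FALSE)
    vpos <- vpos + span + 120L
  }
  chars[ira_start + seq_len(irlen)] <- ira

  # IRA rRNA features (minus arc: annotate on '-')
  add_rrna <- function(name, off, len, strand, copy_start) {
    feats[[length(feats) + 1L]] <<-
      gene_feature(name, "rRNA", strand,
                   list(pc_interval(copy_start + off, copy_start + off + len)))
    genes_tab[[length(genes_tab) + 1L]] <<-
      data.frame(name = name, raw_name = name, ftype = "rRNA",
                 strand = strand, start = copy_start + off,
                 end = copy_start + off + len, exon_bases = len,
                 intron_bases = 0L, region = "ir", stringsAsFactors = FALSE)
  }
  add_rrna("rrn16", 0L, config$rrn16_len, "-", ira_start)
  add_rrna("rrn23", r23_off, config$rrn23_len, "-", ira_start)
  pos <- ira_start + irlen

  # insertion block A (minus arc)
  insa_iv <- NULL
  if (length(insa_idx)) {
    blk_start <- pos
    pos <- pos + GAP_EDGE
    for (j in seq_along(insa_idx)) {
      if (j > 1L) pos <- pos + GAP_BLOCK
      pos <- place_gene(plan[[insa_idx[j]]], pos, "-")
    }
    insa_iv <- pc_interval(blk_start, pos)
  }
  pos <- pos + GAP_SEP
  for (j in seq_along(ssc_idx))
    pos <- place_gene(plan[[ssc_idx[j]]], pos, "-")
  pos <- pos + GAP_SSC_TAIL

  # ---- IRB = reverse complement of IRA with planted mismatches ---------
  irb_start <- pos
  # SSC as the partitioner reports it: the arc remainder between the
  # carved insertion block (or IRA) and IRB
  ssc_iv <- pc_interval(if (!is.null(insa_iv)) insa_iv$end
                        else ira_start + irlen, irb_start)
  irb <- strsplit(reverse_complement(paste(ira, collapse = "")), "")[[1L]]
  # mismatches inside the mirrored 23S gene, >= 100 bases from IR ends
  mir23 <- c(irlen - (r23_off + config$rrn23_len), irlen - r23_off)
  mm_lo <- max(mir23[1L] + 1L, 101L)
  mm_hi <- min(mir23[2L], irlen - 100L)
  mm_pos <- sort(sample(seq.int(mm_lo, mm_hi), config$ir_mismatches))
  for (mp in mm_pos)
    irb[mp] <- setdiff(c("A", "C", "G", "T"), irb[mp])[
      sample.int(3L, 1L)]
  chars[irb_start + seq_len(irlen)] <- irb
  # rRNA features mirrored into IRB (plus arc)
  add_rrna("rrn16", irlen - config$rrn16_len, config$rrn16_len, "+",
           irb_start)
  add_rrna("rrn23", irlen - r23_off - config$rrn23_len, config$rrn23_len,
           "+", irb_start)
  pos <- irb_start + irlen

  # insertion block B (plus arc)
  insb_iv <- NULL
  if (length(insb_idx)) {
    blk_start <- pos
    pos <- pos + GAP_EDGE
    for (j in seq_along(insb_idx)) {
      if (j > 1L) pos <- pos + GAP_BLOCK
      pos <- place_gene(plan[[insb_idx[j]]], pos, "+")
    }
    insb_iv <- pc_interval(blk_start, pos)
  }
  pos <- pos + GAP_SEP
  if (pos != L)
    pc_stop("internal layout error: laid out ", pos, " of ", L, " bases")

  # sharp IR boundaries: force the two base pairs flanking each copy to
  # mismatch, so the planted repeat length is sequence-defined.
  for (t in 0:1) {
    chars[irb_start + irlen + 1L + t] <- chars[ira_start - t]       # left of A / right of B
    chars[irb_start - t] <- chars[ira_start + irlen + 1L + t]       # right of A / left of B
  }

  sequence <- paste(chars, collapse = "")
  genome <- annotated_genome(sprintf("sim_%d", seed), sequence, "circular",
                             feats)

  genes <- do.call(rbind, genes_tab)
  truth <- list(
    seed = seed,
    config = config,
    genome_size = L,
    gc = sum(chars %in% c("G", "C")) / L,
    ir = list(ira = c(ira_start, ira_start + irlen),
              irb = c(irb_start, irb_start + irlen),
              length = irlen, mismatches = config$ir_mismatches,
              mismatch_positions = irb_start + mm_pos - 1L),
    insertions = Filter(Negate(is.null), list(insa_iv, insb_iv)),
    ssc = c(ssc_iv$start, ssc_iv$end),
    strand = list(switch_gene_index = k_switch, consistency = 1),
    vntr = do.call(rbind, vntr_truth),
    genes = genes,
    summary = truth_summary(genes, L, sum(chars %in% c("G", "C")))
  )
  list(genome = genome, truth = truth)
}

# Expected feature-summary row from the generator's own bookkeeping.
truth_summary <- function(genes, L, gc_count) {
  cds <- genes[genes$ftype == "CDS", ]
  trna <- genes[genes$ftype == "tRNA", ]
  rrna <- genes[genes$ftype == "rRNA", ]
  spliced <- cds[cds$intron_bases > 0L, ]
  nonspliced <- cds[cds$intron_bases == 0L, ]
  cds_exon <- sum(cds$exon_bases)
  n_dup <- sum(duplicated(paste(rrna$name, rrna$ftype)))
  covered <- sum(genes$end - genes$start)   # genes never overlap by design
  data.frame(
    genome_size = L,
    gc_percentage = round_half_up(100 * gc_count / L, 2),
    gene_unique_loci = nrow(genes) - n_dup,
    rrna_unique_count = length(unique(rrna$name)),
    rrna_total_bases = sum(rrna$exon_bases),
    trna_unique_count = length(unique(trna$name)),
    trna_total_bases = sum(trna$exon_bases),
    cds_conserved = sum(!grepl("^orf[0-9]+$", cds$name)),
    cds_all = nrow(cds),
    nonspliced_count = nrow(nonspliced),
    nonspliced_bases = sum(nonspliced$exon_bases),
    spliced_count = nrow(spliced),
    spliced_bases = sum(spliced$exon_bases),
    intron_count = sum(genes$intron_bases > 0L),
    intron_bases = sum(genes$intron_bases),
    density = round_half_up(nrow(cds) / (L / 1000), 3),
    avg_len_excl_introns = floor(cds_exon / nrow(cds)),
    coding_pct_excl_introns = round_half_up(100 * cds_exon / L, 1),
    intergenic_bases_excl_rna = L - covered,
    overlapping_bases = 0L,
    stringsAsFactors = FALSE
  )
}

#' Apply random gene-order inversions
#'
#' Picks `k` random runs of adjacent genes and inverts each: the spanned
#' sequence block is reverse-complemented, the features inside are
#' remapped, their strands flipped and their segment order reversed.
#' Each inversion breaks at most two gene adjacencies, which bounds the
#' shared-adjacency statistic from below by `n - 2k`.
#'
#' @param genome an [annotated_genome()] with non-overlapping,
#'   non-origin-wrapping features.
#' @param k number of inversions (>= 0).
#' @param seed integer random seed.
#' @return list with `genome` (rearranged) and `truth` (data.frame of the
#'   inverted gene-index runs and genomic intervals).
#' @export
apply_inversions <- function(genome, k, seed = 1L) {
  set.seed(seed)
  L <- genome_length(genome)
  segments_log <- list()
  for (step in seq_len(k)) {
    feats <- genome$features
    spans <- lapply(feats, feature_span, L = L)
    if (any(vapply(spans, `[[`, TRUE, "wraps")))
      pc_stop("inversions require non-wrapping features")
    ord <- order(vapply(spans, `[[`, 0L, "start"))
    feats <- feats[ord]; spans <- spans[ord]
    n <- length(feats)
    a <- sample.int(n, 1L)
    len <- sample.int(n - a + 1L, 1L)
    b <- a + len - 1L
    s <- spans[[a]]$start
    e <- spans[[b]]$end
    block <- substr(genome$sequence, s + 1L, e)
    newseq <- paste0(substr(genome$sequence, 1L, s),
                     reverse_complement(block),
                     substr(genome$sequence, e + 1L, L))
    for (i in a:b) {
      f <- feats[[i]]
      f$strand <- if (f$strand == "+") "-" else "+"
      f$segments <- rev(lapply(f$segments, function(sg)
        pc_interval(s + (e - sg$end), s + (e - sg$start))))
      feats[[i]] <- f
    }
    genome <- annotated_genome(genome$id, newseq, genome$topology, feats)
    segments_log[[step]] <- data.frame(step = step, from_gene = a,
                                       to_gene = b, start = s, end = e)
  }
  list(genome = genome,
       truth = if (k > 0L) do.call(rbind, segments_log)
               else data.frame(step = integer(0), from_gene = integer(0),
                               to_gene = integer(0), start = integer(0),
                               end = integer(0)))
}

#' The packaged worked-example gene-content fixture
#'
#' Returns the packaged protein-coding content sets for the worked
#' endosymbiotic gene-transfer example: an algal reference set
#' (pyramimonas), the two euglenid plastid sets (euglena, eutreptiella) -
#' whose shared core is a representative stand-in gene list, with the
#' 24-gene missing set and the lineage-specific sets following the
#' published worked-example enumerations - and the transcriptome evidence table
#' (petA, petN, ycf3, clpP, ftsH positive in both sources; ccsA in the
#' euglena source only).
#'
#' @return list with elements `reference` (character), `plastid_sets`
#'   (named list: euglena, eutreptiella), `sets` (all three sets incl.
#'   the reference), `missing` (reference genes absent from both plastid
#'   sets) and `evidence` (data.frame gene/source/present).
#' @export
egt_fixture <- function() {
  sets_path <- system.file("extdata", "egt_fixture_sets.tsv",
                           package = "plastidcomp", mustWork = TRUE)
  ev_path <- system.file("extdata", "egt_fixture_evidence.tsv",
                         package = "plastidcomp", mustWork = TRUE)
  tab <- utils::read.delim(sets_path, comment.char = "#",
                           stringsAsFactors = FALSE)
  tab$gene <- normalize_gene_name(tab$gene)
  sets <- list(
    pyramimonas = tab$gene[tab$pyramimonas == 1L],
    euglena = tab$gene[tab$euglena == 1L],
    eutreptiella = tab$gene[tab$eutreptiella == 1L]
  )
  ev <- utils::read.delim(ev_path, comment.char = "#",
                          stringsAsFactors = FALSE)
  ev$gene <- normalize_gene_name(ev$gene)
  missing <- setdiff(sets$pyramimonas, union(sets$euglena, sets$eutreptiella))
  list(reference = sets$pyramimonas,
       plastid_sets = sets[c("euglena", "eutreptiella")],
       sets = sets, missing = missing, evidence = ev)
}

#' Simulate a gene-fate scenario with planted truth
#'
#' Builds a random reference gene set, assigns each reference gene one of
#' the five reference-relative fates (and optionally adds
#' lineage-specific gains), then constructs the plastid gene sets and the
#' evidence table that encode exactly those fates (no noise model).  Used
#' to verify that [classify_fates()] recovers every planted fate.
#'
#' @param n_genes reference genes (default 40).
#' @param n_gains lineage-specific gains added per lineage (default 2).
#' @param lineages names of the descendant lineages (default two).
#' @param seed integer random seed.
#' @return list with `reference`, `plastid_sets`, `evidence` and `truth`
#'   (data.frame gene/fate).
#' @export
simulate_fate_scenario <- function(n_genes = 40L, n_gains = 2L,
                                   lineages = c("lineageA", "lineageB"),
                                   seed = 1L) {
  set.seed(seed)
  fates <- c("retained_plastid", "lost_post_split",
             "transferred_ancestral_both",
             "transferred_ancestral_lost_in_one", "lost_completely")
  reference <- sprintf("gene%03d", seq_len(n_genes))
  fate <- sample(fates, n_genes, replace = TRUE)
  sets <- stats::setNames(rep(list(character(0)), length(lineages)),
                          lineages)
  ev <- list()
  add_ev <- function(g, src) ev[[length(ev) + 1L]] <<-
    data.frame(gene = g, source = src, present = 1L,
               stringsAsFactors = FALSE)
  for (i in seq_len(n_genes)) {
    g <- reference[i]
    switch(fate[i],
           retained_plastid = for (ln in lineages)
             sets[[ln]] <- c(sets[[ln]], g),
           lost_post_split = {
             keep <- sample(seq_along(lineages),
                            sample(length(lineages) - 1L, 1L))
             for (ln in lineages[keep]) sets[[ln]] <- c(sets[[ln]], g)
           },
           transferred_ancestral_both = for (ln in lineages)
             add_ev(g, ln),
           transferred_ancestral_lost_in_one = {
             keep <- sample(seq_along(lineages),
                            sample(length(lineages) - 1L, 1L))
             for (ln in lineages[keep]) add_ev(g, ln)
           },
           lost_completely = NULL)
  }
  for (ln in lineages)
    sets[[ln]] <- c(sets[[ln]],
                    sprintf("%s_orf%02d", ln, seq_len(n_gains)))
  evidence <- if (length(ev)) do.call(rbind, ev)
              else data.frame(gene = character(0), source = character(0),
                              present = integer(0))
  list(reference = reference, plastid_sets = sets, evidence = evidence,
       truth = data.frame(gene = reference, fate = fate,
                          stringsAsFactors = FALSE))
}

#' Simulate a whole-genome assembly contig table
#'
#' Bimodal coverage model for organelle binning tests: plastid contigs at
#' high fold-coverage, nuclear contigs at low coverage.  The two longest
#' plastid contigs are flagged as homology-identified seeds.
#'
#' @param n_contigs total contigs (default 200).
#' @param n_plastid planted plastid contigs (default 20).
#' @param plastid_cov,nuclear_cov `c(mean, sd)` of the normal coverage
#'   distributions (defaults c(32, 2) and c(5, 1)).
#' @param seed integer random seed.
#' @return `data.frame` with columns `id`, `length`, `coverage`, `seed`
#'   and the truth label `is_plastid`.
#' @export
simulate_contig_table <- function(n_contigs = 200L, n_plastid = 20L,
                                  plastid_cov = c(32, 2),
                                  nuclear_cov = c(5, 1), seed = 1L) {
  set.seed(seed)
  n_nuc <- n_contigs - n_plastid
  tab <- data.frame(
    id = sprintf("contig%03d", seq_len(n_contigs)),
    length = c(sample(600:30000, n_plastid, replace = TRUE),
               sample(100:5000, n_nuc, replace = TRUE)),
    coverage = pmax(0, c(stats::rnorm(n_plastid, plastid_cov[1L],
                                      plastid_cov[2L]),
                         stats::rnorm(n_nuc, nuclear_cov[1L],
                                      nuclear_cov[2L]))),
    is_plastid = rep(c(TRUE, FALSE), c(n_plastid, n_nuc)),
    stringsAsFactors = FALSE
  )
  seeds <- tab$id[tab$is_plastid][order(-tab$length[tab$is_plastid])][1:2]
  tab$seed <- tab$id %in% seeds
  tab
}
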