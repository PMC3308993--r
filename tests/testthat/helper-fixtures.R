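# Shared fixtures and independent oracles, built in code.

# A small but fully structured simulation config so I/O and round-trip
# tests stay fast; the full-size default config is exercised in the
# acceptance suite.
small_config <- function(...) {
  sim_config(genome_size = 30000L, n_cds = 12L, n_orf = 1L, n_trna = 6L,
             n_introns = 1L, ir_length = 3000L,
             rrn16_len = 700L, rrn23_len = 1400L,
             ins_a_cds = 3L, ins_a_trna = 1L, ins_b_trna = 1L, ...)
}

# Circular genome with named genes laid out in the given order.
# Each gene is `len` bases with `gap` intergenic bases; strands cycle
# through `strands`.
genome_from_order <- function(order, len = 30L, gap = 10L,
                              strands = "+", ftype = "CDS",
                              topology = "circular", id = "toy") {
  n <- length(order)
  strands <- rep_len(strands, n)
  L <- n * (len + gap) + gap
  feats <- vector("list", n)
  pos <- gap
  for (i in seq_len(n)) {
    feats[[i]] <- gene_feature(order[i], ftype, strands[i],
                               list(pc_interval(pos, pos + len)))
    pos <- pos + len + gap
  }
  annotated_genome(id, substr(strrep("ACGT", ceiling(L / 4) + 1L), 1L, L),
                   topology, feats)
}

# Independent adjacency oracle: enumerates neighbour pairs by explicit
# rotation of the circular order, counting shared pairs with nested loops.
oracle_shared_adjacency <- function(order_a, order_b, circular = TRUE) {
  pairs_of <- function(ord) {
    n <- length(ord)
    out <- character(0)
    hi <- if (circular) n else n - 1L
    for (i in seq_len(hi)) {
      x <- ord[i]; y <- ord[if (i == n) 1L else i + 1L]
      out <- c(out, paste(sort(c(x, y)), collapse = "|"))
    }
    out
  }
  pa <- pairs_of(order_a); pb <- pairs_of(order_b)
  used <- logical(length(pb))
  shared <- 0L
  for (p in pa) {
    hit <- which(!used & pb == p)
    if (length(hit)) { used[hit[1L]] <- TRUE; shared <- shared + 1L }
  }
  shared
}

# Independent strand-switch oracle: tries every boundary pair and counts
# majority-strand genes per arc directly.
oracle_strand_consistency <- function(strands) {
  n <- length(strands)
  if (length(unique(strands)) == 1L) return(1)
  best <- 0L
  for (b1 in 0:(n - 1L)) {
    for (b2 in (b1 + 1L):n) {
      inside <- strands[(b1 + 1L):b2]
      outside <- strands[setdiff(seq_len(n), (b1 + 1L):b2)]
      score <- max(sum(inside == "+"), sum(inside == "-")) +
        max(sum(outside == "+"), sum(outside == "-"))
      best <- max(best, score)
    }
  }
  best / n
}

# Plant an inverted repeat into a random sequence: copy seq[a0..a0+len)
# reverse-complemented to b0, apply `n_sub` substitutions (>= 100 bases
# from the copy ends) and force two mismatching base pairs at each
# boundary so the planted length is sequence-defined.
plant_inverted_repeat <- function(L, ir_len, a0, b0, n_sub, seed) {
  set.seed(seed)
  chars <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
  src <- paste(chars[(a0 + 1):(a0 + ir_len)], collapse = "")
  copy <- strsplit(as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(src))), "")[[1L]]
  sub_at <- sample(seq.int(101L, ir_len - 100L), n_sub)
  for (p in sub_at) copy[p] <- setdiff(c("A", "C", "G", "T"), copy[p])[1L]
  chars[(b0 + 1):(b0 + ir_len)] <- copy
  for (t in 0:1) {
    chars[b0 + ir_len + 1L + t] <- chars[a0 - t]
    chars[b0 - t] <- chars[a0 + ir_len + 1L + t]
  }
  paste(chars, collapse = "")
}
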