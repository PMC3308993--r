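test_that("simulation is deterministic per (config, seed)", {
  a <- simulate_genome(small_config(), seed = 7)
  b <- simulate_genome(small_config(), seed = 7)
  pa <- withr::local_tempfile(fileext = ".gb")
  pb <- withr::local_tempfile(fileext = ".gb")
  write_genbank(a$genome, pa)
  write_genbank(b$genome, pb)
  expect_identical(readLines(pa), readLines(pb))
  c_ <- simulate_genome(small_config(), seed = 8)
  expect_false(identical(a$genome$sequence, c_$genome$sequence))
})

test_that("summary of a simulated genome equals planted truth", {
  sim <- simulate_genome(small_config(), seed = 2)
  hits <- detect_inverted_repeats(sim$genome)
  part <- partition_quadripartite(sim$genome, hits[1, ])
  s <- summarize_genome(sim$genome, part)
  tr <- sim$truth$summary
  for (cn in names(tr))
    expect_equal(s[[cn]], tr[[cn]], info = cn)
})

test_that("GC control holds within a point at 60 kb", {
  sim <- simulate_genome(sim_config(), seed = 3)
  expect_lt(abs(gc_percentage(sim$genome) - 34), 1)
})

test_that("infeasible packing is a hard error", {
  expect_error(simulate_genome(sim_config(genome_size = 20000L), seed = 1),
               "infeasible")
})

test_that("inversions rearrange the recorded gene runs", {
  g <- genome_from_order(c("a", "b", "c", "d", "e"), len = 30, gap = 10)
  inv <- apply_inversions(g, 1, seed = 5)
  tr <- inv$truth
  expect_equal(nrow(tr), 1)
  ord0 <- c("a", "b", "c", "d", "e")
  expected <- ord0
  expected[tr$from_gene:tr$to_gene] <- rev(ord0[tr$from_gene:tr$to_gene])
  got <- plastidcomp:::retained_gene_order(
    inv$genome, synteny_policy(collapse_ir = FALSE))
  expect_equal(got, expected)
  # inverted genes flip strand
  flipped <- vapply(inv$genome$features, `[[`, "", "strand")
  expect_setequal(unique(flipped), c("+", "-"))
  # k = 0 leaves the genome untouched
  same <- apply_inversions(g, 0, seed = 5)
  expect_identical(same$genome$sequence, g$sequence)
  expect_equal(nrow(same$truth), 0)
})

test_that("inverted blocks carry their sequence with them", {
  sim <- simulate_genome(small_config(), seed = 6)
  inv <- apply_inversions(sim$genome, 3, seed = 6)
  g2 <- inv$genome
  L <- genome_length(g2)
  # every CDS still starts with ATG on its own strand
  for (f in g2$features) {
    if (f$ftype != "CDS") next
    segs <- if (f$strand == "-") rev(f$segments) else f$segments
    span <- if (f$strand == "-") segs[[length(segs)]] else segs[[1L]]
    s <- plastidcomp:::iv_sequence(g2$sequence, span)
    codon <- if (f$strand == "+") substr(s, 1, 3)
             else reverse_complement(substr(s, nchar(s) - 2, nchar(s)))
    expect_equal(codon, "ATG", info = f$name)
  }
})

test_that("the packaged fixture matches the worked-example enumerations", {
  fx <- egt_fixture()
  expect_length(fx$missing, 24)
  expect_length(setdiff(fx$sets$eutreptiella, fx$sets$euglena), 5)
  expect_length(setdiff(fx$sets$euglena, fx$sets$eutreptiella), 8)
  pos <- with(fx$evidence, split(source[present == 1], gene[present == 1]))
  both_pos <- names(pos)[vapply(pos, function(s)
    all(c("euglena", "eutreptiella") %in% s), TRUE)]
  expect_setequal(both_pos, c("petA", "petN", "ycf3", "clpP", "ftsH"))
  # ccsA positive in the euglena source only
  ccsa <- fx$evidence[fx$evidence$gene == "ccsA" & fx$evidence$present == 1, ]
  expect_equal(ccsa$source, "euglena")
})

test_that("planted fate scenarios are encoded faithfully", {
  sc <- simulate_fate_scenario(n_genes = 25, seed = 42)
  # genes planted as plastid-retained or post-split-lost are in the sets
  in_sets <- unique(unlist(sc$plastid_sets))
  for (i in seq_len(nrow(sc$truth))) {
    g <- sc$truth$gene[i]
    if (sc$truth$fate[i] %in% c("retained_plastid", "lost_post_split"))
      expect_true(g %in% in_sets)
    else
      expect_false(g %in% in_sets)
  }
})
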