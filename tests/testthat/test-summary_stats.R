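test_that("GC percentage counts ambiguity codes in the denominator only", {
  expect_equal(gc_percentage("ATAT"), 0)
  expect_equal(gc_percentage("ACGT"), 50)
  expect_equal(gc_percentage("ACGN"), 50)  # N in denominator only
  expect_equal(gc_percentage("acgt"), 50)
  expect_error(gc_percentage(""), "empty")
})

test_that("summary of a hand-built genome matches hand computation", {
  g <- annotated_genome("hand", strrep("ACGT", 250), "circular", list(
    gene_feature("psbA", "CDS", "+", list(pc_interval(0, 300))),
    gene_feature("rbcL", "CDS", "-", list(pc_interval(400, 700)))))
  s <- summarize_genome(g)
  expect_equal(s$cds_all, 2)
  expect_equal(s$cds_conserved, 2)
  expect_equal(s$density, 2.000)
  expect_equal(s$coding_pct_excl_introns, 60.0)
  expect_equal(s$avg_len_excl_introns, 300)
  expect_equal(s$intergenic_bases_excl_rna, 400)
  expect_equal(s$overlapping_bases, 0)
})

test_that("a featureless genome summarizes to zeros", {
  g <- annotated_genome("empty", strrep("ACGT", 250), "circular")
  s <- summarize_genome(g)
  expect_equal(s$cds_all, 0)
  expect_equal(s$gene_unique_loci, 0)
  expect_equal(s$density, 0)
  expect_equal(s$avg_len_excl_introns, 0)
  expect_equal(s$intergenic_bases_excl_rna, 1000)
})

test_that("overlapping bases are counted once and spliced CDS split out", {
  g <- annotated_genome("ovl", strrep("ACGT", 500), "circular", list(
    gene_feature("psbA", "CDS", "+", list(pc_interval(0, 300))),
    gene_feature("psbB", "CDS", "+", list(pc_interval(250, 550))),
    gene_feature("psaA", "CDS", "+",
                 list(pc_interval(600, 900), pc_interval(1000, 1100)))))
  s <- summarize_genome(g)
  expect_equal(s$overlapping_bases, 50)
  expect_equal(s$spliced_count, 1)
  expect_equal(s$nonspliced_count, 2)
  expect_equal(s$spliced_bases, 400)
  expect_equal(s$intron_count, 1)
  expect_equal(s$intron_bases, 100)
  expect_equal(s$intergenic_bases_excl_rna, 2000 - 550 - 500)
})

test_that("IR duplicates collapse only when a partition is given", {
  mk <- function(name, ftype, at)
    gene_feature(name, ftype, "+", list(pc_interval(at, at + 100)))
  g <- annotated_genome("ir", strrep("ACGT", 1000), "circular", list(
    mk("rrn16", "rRNA", 100), mk("rrn23", "rRNA", 250),
    mk("rrn16", "rRNA", 2100), mk("rrn23", "rRNA", 2250),
    mk("psbA", "CDS", 1200)))
  part <- list(ira = pc_interval(50, 500), irb = pc_interval(2050, 2500))
  s_no <- summarize_genome(g)
  s_ir <- summarize_genome(g, part)
  expect_equal(s_no$gene_unique_loci, 5)   # no partition: all loci counted
  expect_equal(s_ir$gene_unique_loci, 3)   # both rRNA pairs collapse
  expect_equal(s_ir$rrna_unique_count, 2)
  expect_equal(s_ir$rrna_total_bases, 400) # all copies still summed
  # collapsing never increases any count
  num <- vapply(names(s_no), function(cn) is.numeric(s_no[[cn]]), TRUE)
  expect_true(all(unlist(s_ir[num]) <= unlist(s_no[num])))
  # out-of-genome IR intervals are rejected
  bad <- list(ira = pc_interval(50, 500), irb = pc_interval(4100, 4200))
  expect_error(summarize_genome(g, bad), "outside")
})

test_that("coverage classes never exceed the genome size", {
  sim <- simulate_genome(small_config(), seed = 5)
  s <- summarize_genome(sim$genome)
  covered <- s$genome_size - s$intergenic_bases_excl_rna
  expect_lte(covered, s$genome_size)
  expect_lte(s$overlapping_bases, covered)
})
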