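test_that("intervals obey circular arithmetic", {
  iv <- pc_interval(0, 300)
  expect_equal(iv_length(iv), 300)
  w <- pc_interval(95, 5, wraps = TRUE)
  expect_equal(iv_length(w, 100), 10)
  expect_equal(iv_positions(w, 100), c(96:100, 1:5))
  expect_error(pc_interval(10, 10), "start < end")
  expect_error(pc_interval(-1, 5), ">= 0")
  # wrapping interval length is always > 0
  expect_gt(iv_length(pc_interval(99, 0, wraps = TRUE), 100), 0)
})

test_that("1-based inclusive coordinates round-trip losslessly", {
  set.seed(42)
  L <- 10000L
  for (i in 1:1000) {
    first <- sample.int(L, 1L)
    last <- sample(seq.int(first, L), 1L)
    iv <- iv_from_one_based(first, last, L)
    expect_equal(unname(iv_to_one_based(iv)), c(first, last))
  }
  # wrapping range on a circle
  iv <- iv_from_one_based(9990L, 20L, L)
  expect_true(iv$wraps)
  expect_equal(iv_length(iv, L), 31L)
})

test_that("exon + intron bases always equal the span", {
  f1 <- gene_feature("psbA", "CDS", "+", list(pc_interval(100, 1000)))
  expect_equal(exon_bases(f1), 900)
  expect_equal(intron_bases(f1), 0)
  # two segments of 900 and 400 bases spanning 2780 bases -> intron 1480
  f2 <- gene_feature("psaA", "CDS", "+",
                     list(pc_interval(100, 1000), pc_interval(2480, 2880)))
  expect_equal(exon_bases(f2), 1300)
  expect_equal(intron_bases(f2), 1480)
  # minus strand: segments in transcription order (reverse genomic)
  f3 <- gene_feature("rpoB", "CDS", "-",
                     list(pc_interval(500, 800), pc_interval(100, 300)))
  sp <- feature_span(f3)
  expect_equal(c(sp$start, sp$end), c(100, 800))
  expect_equal(exon_bases(f3) + intron_bases(f3), iv_length(sp))
})

test_that("gene-name normalization is canonical and idempotent", {
  expect_equal(normalize_gene_name("PsbA"), "psbA")
  expect_equal(normalize_gene_name("ycf13"), "mat1")
  expect_equal(normalize_gene_name("Rpl3"), "ycf65")
  expect_equal(normalize_gene_name("RPOC1"), "rpoC1")
  expect_equal(normalize_gene_name("orf248"), "orf248")
  expect_false(gene_feature("orf248", "CDS", "+",
                            list(pc_interval(0, 99)))$conserved)
  expect_true(gene_feature("psbA", "CDS", "+",
                           list(pc_interval(0, 99)))$conserved)
  # tRNA canonicalization
  expect_equal(normalize_gene_name("tRNA-Ala(ugc)"), "trnA-UGC")
  expect_equal(normalize_gene_name("tRNA-Ala"), "trnA")
  expect_equal(normalize_gene_name("trnA-UGC"), "trnA-UGC")
  # idempotency over a mixed label set
  labels <- c("PsbA", "ycf13", "orf248", "tRNA-Ala(ugc)", "RBCL", "mat1",
              "rrn16", "Ycf65", "rpl3", "trnfM", "atpI", "unnamed")
  once <- normalize_gene_name(labels)
  expect_equal(normalize_gene_name(once), once)
})

test_that("reverse complement is IUPAC-aware and involutive", {
  expect_equal(reverse_complement("ACGT"), "ACGT")
  expect_equal(reverse_complement("AAAC"), "GTTT")
  expect_equal(reverse_complement("ANNC"), "GNNT")
  expect_error(reverse_complement("AXQ"), "non-IUPAC")
  set.seed(1)
  for (i in 1:20) {
    s <- paste(sample(c("A", "C", "G", "T", "N"), 200, replace = TRUE),
               collapse = "")
    expect_equal(reverse_complement(reverse_complement(s)), s)
  }
})

test_that("GenBank records parse into annotated genomes", {
  gb <- c(
    "LOCUS       testrec           2880 bp    DNA     circular PLN 01-JAN-2000",
    "DEFINITION  synthetic test record.",
    "ACCESSION   testrec",
    "FEATURES             Location/Qualifiers",
    "     source          1..2880",
    "     CDS             join(101..1000,2481..2880)",
    "                     /gene=\"psaA\"",
    "     tRNA            complement(1101..1172)",
    "                     /gene=\"tRNA-Ala(ugc)\"",
    "     misc_feature    1..10",
    "ORIGIN",
    plastidcomp:::format_origin(strrep("ACGT", 720)),
    "//")
  path <- withr::local_tempfile(fileext = ".gb")
  writeLines(gb, path)
  g <- read_genbank(path)
  expect_equal(g$topology, "circular")
  expect_equal(genome_length(g), 2880)
  expect_length(g$features, 2)          # misc_feature ignored
  cds <- g$features[[1]]
  expect_equal(exon_bases(cds), 1300)
  expect_equal(intron_bases(cds), 1480) # span - exons
  trna <- g$features[[2]]
  expect_equal(trna$strand, "-")
  expect_equal(trna$name, "trnA-UGC")

  # zero features -> empty feature list
  gb0 <- gb[-(5:10)]
  writeLines(gb0, path)
  expect_length(read_genbank(path)$features, 0)

  # missing sequence -> hard error
  writeLines(gb[1:9], path)
  expect_error(read_genbank(path), "ORIGIN")

  # feature outside the sequence -> hard error naming the feature
  gb_bad <- sub("join\\(101\\.\\.1000,2481\\.\\.2880\\)", "2801..3100", gb)
  writeLines(gb_bad, path)
  expect_error(read_genbank(path), "psaA")
})

test_that("GFF3 coordinates convert at the boundary", {
  fa <- withr::local_tempfile(fileext = ".fa")
  gff <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c(">chr1", strrep("ACGT", 100)), fa)
  writeLines(c("##gff-version 3",
               "chr1\tx\tCDS\t1\t300\t.\t+\t0\tID=g1;Name=psbA",
               "chr1\tx\tCDS\t320\t355\t.\t-\t0\tID=g2;Name=rpl2",
               "chr1\tx\tweird\t1\t5\t.\t+\t.\tID=g3"), gff)
  expect_warning(g <- read_gff_fasta(gff, fa), "weird")
  iv <- g$features[[1]]$segments[[1]]
  expect_equal(c(iv$start, iv$end), c(0, 300))
  expect_equal(g$features[[2]]$strand, "-")

  # mismatching sequence IDs -> hard error
  writeLines(c("##gff-version 3",
               "other\tx\tCDS\t1\t30\t.\t+\t0\tID=g1"), gff)
  expect_error(read_gff_fasta(gff, fa), "do not match")
})

test_that("write/read round-trips preserve the feature set", {
  sim <- simulate_genome(small_config(), seed = 41)
  g <- sim$genome
  same_features <- function(a, b) {
    all(mapply(function(x, y)
      identical(x$name, y$name) && identical(x$ftype, y$ftype) &&
        identical(x$strand, y$strand) && identical(x$segments, y$segments),
      a$features, b$features))
  }
  gb <- withr::local_tempfile(fileext = ".gb")
  write_genbank(g, gb)
  g2 <- read_genbank(gb)
  expect_identical(g2$sequence, g$sequence)
  expect_identical(g2$topology, g$topology)
  expect_true(same_features(g, g2))

  gff <- withr::local_tempfile(fileext = ".gff3")
  fa <- withr::local_tempfile(fileext = ".fa")
  write_gff_fasta(g, gff, fa)
  g3 <- read_gff_fasta(gff, fa)
  expect_identical(g3$sequence, g$sequence)
  expect_true(same_features(g, g3))
})
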