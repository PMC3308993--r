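test_that("content partition performs exact set algebra", {
  p <- content_partition(list(A = c("a", "b", "c"), B = c("b", "c", "d")))
  expect_equal(p$A, "a")
  expect_equal(p$B, "d")
  expect_setequal(p$`A&B`, c("b", "c"))
  # regions are disjoint and cover the union
  expect_equal(sort(unlist(p, use.names = FALSE)), c("a", "b", "c", "d"))
  expect_error(content_partition(list(A = "a")), "2-4")
})

test_that("content partition equals membership-vector grouping", {
  set.seed(3)
  universe <- sprintf("g%03d", 1:60)
  for (case in 1:100) {
    sets <- lapply(1:3, function(i) sample(universe, sample(5:40, 1)))
    names(sets) <- c("X", "Y", "Z")
    p <- content_partition(sets)
    # oracle: group genes by their membership vector directly
    genes <- sort(unique(unlist(sets)))
    for (g in genes) {
      sig <- paste(names(sets)[vapply(sets, function(s) g %in% s, TRUE)],
                   collapse = "&")
      expect_true(g %in% p[[sig]], info = paste(case, g, sig))
    }
    expect_equal(sum(lengths(p)), length(genes))
  }
})

test_that("genomes feed the partition through normalized CDS names", {
  ga <- genome_from_order(c("psbA", "rbcL", "trnA-UGC"), id = "ga")
  ga$features[[3]]$ftype <- "tRNA"
  gb <- genome_from_order(c("PsbA", "ycf13"), id = "gb")
  p <- content_partition(list(ga = ga, gb = gb))
  expect_equal(p$ga, "rbcL")            # tRNA excluded (protein_only)
  expect_equal(p$gb, "mat1")            # ycf13 -> mat1
  expect_equal(p$`ga&gb`, "psbA")       # case-folded match
})

test_that("fate classification follows set membership plus evidence", {
  ref <- c("kept", "partial", "tboth", "tone", "gone")
  sets <- list(s1 = c("kept", "partial", "extra1"), s2 = c("kept"))
  ev <- data.frame(gene = c("tboth", "tboth", "tone"),
                   source = c("s1", "s2", "s1"), present = 1)
  rep_ <- classify_fates(ref, sets, ev)
  fate_of <- function(g) rep_$fate[rep_$gene == g]
  expect_equal(fate_of("kept"), "retained_plastid")
  expect_equal(fate_of("partial"), "lost_post_split")
  expect_equal(fate_of("tboth"), "transferred_ancestral_both")
  expect_equal(fate_of("tone"), "transferred_ancestral_lost_in_one")
  expect_equal(fate_of("gone"), "lost_completely")
  expect_equal(fate_of("extra1"), "lineage_specific_gain")
  # evidence for unknown genes is ignored with a warning
  ev2 <- rbind(ev, data.frame(gene = "mystery", source = "s1", present = 1))
  expect_warning(rep2 <- classify_fates(ref, sets, ev2), "mystery")
  expect_equal(rep2$fate, rep_$fate)
  # unknown evidence source is a hard error
  ev3 <- data.frame(gene = "tboth", source = "nope", present = 1)
  expect_error(classify_fates(ref, sets, ev3), "nope")
})

test_that("an empty missing set leaves every gene retained", {
  ref <- c("a", "b", "c")
  rep_ <- classify_fates(ref, list(x = ref, y = ref))
  expect_true(all(rep_$fate == "retained_plastid"))
  cnt <- fate_counts(rep_)
  expect_equal(sum(cnt[c("transferred_ancestral_both",
                         "transferred_ancestral_lost_in_one",
                         "lost_completely")]), 0)
})

test_that("transfer/loss categories partition the missing set", {
  for (sd in 1:10) {
    sc <- simulate_fate_scenario(n_genes = 30, seed = sd)
    rep_ <- classify_fates(sc$reference, sc$plastid_sets, sc$evidence)
    cnt <- fate_counts(rep_)
    missing <- setdiff(sc$reference, unlist(sc$plastid_sets))
    expect_equal(sum(cnt[c("transferred_ancestral_both",
                           "transferred_ancestral_lost_in_one",
                           "lost_completely")]), length(missing))
    # classification is invariant to evidence row order
    if (nrow(sc$evidence) > 1) {
      shuf <- sc$evidence[rev(seq_len(nrow(sc$evidence))), ]
      rep2 <- classify_fates(sc$reference, sc$plastid_sets, shuf)
      expect_equal(rep2$fate, rep_$fate)
    }
  }
})

test_that("search hits threshold into evidence at the e-value cutoff", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene\tsource\tevalue",
               "PsbA\ts1\t1e-30",
               "psbA\ts1\t1e-5",
               "rbcL\ts2\t1e-3"), path)
  ev <- read_search_evidence(path)
  expect_equal(nrow(ev), 2)             # best hit per (gene, source)
  expect_true(ev$present[ev$gene == "psbA"])
  expect_false(ev$present[ev$gene == "rbcL"])
})
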