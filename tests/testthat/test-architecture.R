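test_that("a planted inverted repeat is recovered exactly", {
  # random 50 kb sequence with a 5000 bp segment copied in reverse
  # complement with 3 substitutions
  seq <- plant_inverted_repeat(50000L, 5000L, a0 = 10000L, b0 = 30000L,
                               n_sub = 3L, seed = 7)
  hits <- detect_inverted_repeats(seq)
  expect_equal(nrow(hits), 1)
  expect_equal(hits$length, 5000)
  expect_equal(hits$mismatches, 3)
  expect_equal(c(hits$start_a, hits$end_a), c(10000, 15000))
  expect_equal(c(hits$start_b, hits$end_b), c(30000, 35000))
})

test_that("sequences without long repeats yield an empty result", {
  set.seed(99)
  seq <- paste(sample(c("A", "C", "G", "T"), 20000, replace = TRUE),
               collapse = "")
  expect_equal(nrow(detect_inverted_repeats(seq)), 0)
  # min_len larger than the genome is empty, not an error
  expect_equal(nrow(detect_inverted_repeats(seq, min_len = 1e6)), 0)
})

test_that("detection is symmetric under reverse complement", {
  for (sd in 1:3) {
    seq <- plant_inverted_repeat(30000L, 2500L, a0 = 5000L, b0 = 20000L,
                                 n_sub = 2L, seed = sd)
    h1 <- detect_inverted_repeats(seq)
    h2 <- detect_inverted_repeats(reverse_complement(seq))
    expect_equal(h2$length[1], h1$length[1])
    expect_equal(h2$mismatches[1], h1$mismatches[1])
  }
})

test_that("quadripartite partition splits the circle into tiling regions", {
  g <- annotated_genome("toy", strrep("ACGT", 25), "circular")
  hit <- data.frame(start_a = 10, end_a = 20, start_b = 60, end_b = 100,
                    length = 10, mismatches = 0)
  p <- partition_quadripartite(g, hit)
  expect_equal(iv_length(p$ira), 10)
  expect_equal(iv_length(p$irb), 40)
  # arcs: [20,60) of 40 and [0,10) of 10 -> ssc is the shorter
  expect_equal(iv_length(p$ssc, 100), 10)
  expect_equal(iv_length(p$lsc, 100), 40)
  expect_false(p$degenerate)
  total <- iv_length(p$ira) + iv_length(p$irb) + iv_length(p$lsc, 100) +
    iv_length(p$ssc, 100)
  expect_equal(total, 100)

  # adjacent repeat copies: zero-length arc, flagged degenerate
  hit2 <- data.frame(start_a = 10, end_a = 20, start_b = 20, end_b = 30)
  p2 <- partition_quadripartite(g, hit2)
  expect_true(p2$degenerate)
  expect_null(p2$ssc)

  lin <- annotated_genome("lin", "ACGTACGT", "linear")
  expect_error(partition_quadripartite(lin, hit), "circular")
})

test_that("planted IR architecture is recovered from simulator output", {
  sim <- simulate_genome(small_config(), seed = 13)
  g <- sim$genome; tr <- sim$truth; L <- genome_length(g)
  hits <- detect_inverted_repeats(g)
  expect_equal(c(hits$start_a[1], hits$end_a[1]), tr$ir$ira)
  expect_equal(c(hits$start_b[1], hits$end_b[1]), tr$ir$irb)
  expect_equal(hits$mismatches[1], tr$ir$mismatches)
  p <- partition_quadripartite(g, hits[1, ])
  expect_equal(c(p$ssc$start, p$ssc$end), tr$ssc)
  expect_equal(length(p$insertions), length(tr$insertions))
  for (i in seq_along(tr$insertions)) {
    expect_equal(p$insertions[[i]]$start, tr$insertions[[i]]$start)
    expect_equal(p$insertions[[i]]$end, tr$insertions[[i]]$end)
  }
  total <- iv_length(p$ira) + iv_length(p$irb) + iv_length(p$lsc, L) +
    iv_length(p$ssc, L) +
    sum(vapply(p$insertions, iv_length, 0L, genome_length = L))
  expect_equal(total, L)
})

test_that("strand-switch search finds planted two-arc layouts", {
  g <- genome_from_order(sprintf("g%02d", 1:30),
                         strands = rep(c("+", "-"), c(20, 10)))
  sw <- detect_strand_switch(g)
  expect_equal(sw$consistency, 1)
  # boundaries (0, 20) on the circle: the switch sits after gene 20 and
  # after gene 30 (the 30/1 wrap boundary)
  expect_equal(sw$boundaries, c(0, 20))
  expect_length(sw$switch_points, 2)
  # switch positions fall in the 30/1 and 20/21 intergenic gaps
  gene_end <- function(i) 10 + (i - 1) * 40 + 30
  expect_true(sw$switch_points[2] > gene_end(20) &&
                sw$switch_points[2] < gene_end(20) + 10)

  all_plus <- genome_from_order(letters[1:5], strands = "+")
  sw2 <- detect_strand_switch(all_plus)
  expect_equal(sw2$consistency, 1)
  expect_length(sw2$switch_points, 0)

  expect_error(detect_strand_switch(
    annotated_genome("e", "ACGT", "circular")), "2 features")
})

test_that("strand-switch search equals the brute-force oracle", {
  set.seed(7)
  for (case in 1:20) {
    n <- sample(5:40, 1)
    strands <- sample(c("+", "-"), n, replace = TRUE)
    g <- genome_from_order(sprintf("g%02d", seq_len(n)), strands = strands)
    sw <- detect_strand_switch(g)
    expect_equal(sw$consistency, oracle_strand_consistency(strands),
                 info = paste("case", case))
  }
})

test_that("tandem repeats report primitive periods and copy numbers", {
  tr <- find_tandem_repeats("TTAGGGTTAGGGTTAGGGTTA", min_period = 5)
  expect_equal(nrow(tr), 1)
  expect_equal(tr$period, 6)
  expect_equal(tr$copies, 3.5)
  expect_equal(tr$unit, "TTAGGG")
  # homopolymer: true period below min_period, nothing reported
  expect_equal(nrow(find_tandem_repeats(strrep("A", 40), min_period = 5)), 0)
  # dimer repeat scanned at a multiple of its primitive period: suppressed
  expect_equal(nrow(find_tandem_repeats(strrep("ATGCC", 8),
                                        min_period = 10)), 0)
})

test_that("planted tandem repeats are recovered from the IR spacer", {
  sim <- simulate_genome(small_config(), seed = 21)
  tr <- sim$truth
  ira_seq <- substr(sim$genome$sequence, tr$ir$ira[1] + 1, tr$ir$ira[2])
  found <- find_tandem_repeats(ira_seq)
  found$start <- found$start + tr$ir$ira[1]
  for (i in seq_len(nrow(tr$vntr))) {
    hit <- found[found$period == tr$vntr$period[i] &
                   found$start == tr$vntr$start[i], ]
    expect_equal(nrow(hit), 1, info = paste("vntr", i))
    expect_equal(hit$copies, tr$vntr$copies[i])
    expect_equal(hit$unit, tr$vntr$unit[i])
  }
})
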