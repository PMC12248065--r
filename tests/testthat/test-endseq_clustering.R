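# Cluster definition, PAS assignment and the internal-priming filter
# battery, checked against brute-force oracles and hand genomes.

test_that("coverage clustering matches the worked boundary cases", {
  # one 3-wide run, total 38, retained
  r <- cluster_coverage(c(0, 12, 15, 11, 0))
  expect_equal(r, data.frame(start = 2L, end = 4L, total = 38))
  # total 22 >= 20: retained
  expect_equal(nrow(cluster_coverage(c(0, 11, 11, 0))), 1)
  # a sub-threshold position splits the run; both halves die (< 20)
  expect_equal(nrow(cluster_coverage(c(0, 11, 8, 11, 0))), 0)
  # all positions at or below the per-base threshold: nothing
  expect_equal(nrow(cluster_coverage(rep(10, 50))), 0)
})

test_that("coverage clustering equals the position-scan oracle on random vectors", {
  set.seed(31)
  for (i in 1:300) {
    cov <- sample(0:100, sample(20:200, 1), replace = TRUE)
    got <- cluster_coverage(cov)
    exp <- oracle_clusters(cov)
    expect_equal(got$start, exp$start)
    expect_equal(got$end, exp$end)
    expect_equal(got$total, exp$total)
  }
})

test_that("PAS assignment takes the coverage argmax, 3'-most on ties", {
  pos <- 101:104
  cov <- c(12, 30, 30, 11)
  expect_equal(assign_pas(pos, cov, "+"), 103)  # highest coordinate
  expect_equal(assign_pas(pos, cov, "-"), 102)  # 3'-most in tx orientation
  expect_equal(assign_pas(55L, 7L, "+"), 55)    # single position
})

test_that("call_clusters pools samples, strands separate, counts per sample", {
  ends <- data.table::rbindlist(lapply(c("s1", "s2"), function(s) {
    data.table::data.table(
      chrom = "chrT",
      pos = rep(c(100:102, 301:302), times = c(6, 6, 6, 6, 6)),
      strand = "+", sample_id = s)
  }))
  # pooled coverage 12 at each position; minus-strand reads elsewhere
  ends_m <- data.table::data.table(chrom = "chrT", pos = rep(101:102, each = 12),
                                   strand = "-", sample_id = "s1")
  cl <- call_clusters(rbind(ends, ends_m))
  expect_equal(nrow(cl$clusters), 3)
  plus <- cl$clusters[cl$clusters$strand == "+", ]
  expect_equal(sort(plus$start), c(100, 301))
  expect_equal(unname(rowSums(cl$counts)), cl$clusters$total_reads)
  # per-sample split is even for the plus clusters
  expect_true(all(cl$counts[plus$cluster_id, "s1"] ==
                    cl$counts[plus$cluster_id, "s2"]))
  # empty input
  empty <- call_clusters(ends[0])
  expect_equal(nrow(empty$clusters), 0)
})

test_that("A-run filter is strict at 6 and reverse-complement aware", {
  # pas at 20 (+): downstream begins at 21
  g7 <- chr_genome(paste0(strrep("G", 20), "AAAAAAAC", strrep("G", 20)))
  g6 <- chr_genome(paste0(strrep("G", 20), "AAAAAACC", strrep("G", 20)))
  cl <- make_clusters(data.frame(
    cluster_id = "c1", chrom = "chrT", start = 15L, end = 20L,
    strand = "+", total_reads = 100, pas = 20L))
  expect_true(filter_a_run(cl, g7))     # 7 consecutive A: removed
  expect_false(filter_a_run(cl, g6))    # 6 A: kept (strictly more than 6)

  # minus strand: reference shows 7 T upstream -> 7 sense A downstream
  gm <- chr_genome(paste0(strrep("G", 12), "GTTTTTTT", strrep("G", 20)))
  clm <- make_clusters(data.frame(
    cluster_id = "c1", chrom = "chrT", start = 21L, end = 26L,
    strand = "-", total_reads = 100, pas = 21L))
  expect_true(filter_a_run(clm, gm))
  # independent check: sense downstream really is 7 A then C
  sense <- get_seq(gm, "chrT", 11, 20, "-")
  expect_equal(substr(sense, 1, 8), "AAAAAAAC")
})

test_that("A-content filter counts sense-strand A in the 10 nt past the cluster", {
  g8 <- chr_genome(paste0(strrep("G", 30), "AAAAAAAAGC", strrep("G", 10)))
  g7 <- chr_genome(paste0(strrep("G", 30), "AAAAAAAGGC", strrep("G", 10)))
  cl <- make_clusters(data.frame(
    cluster_id = "c1", chrom = "chrT", start = 25L, end = 30L,
    strand = "+", total_reads = 50, pas = 28L))
  expect_true(filter_a_content(cl, g8))   # 8 of 10: removed
  expect_false(filter_a_content(cl, g7))  # 7 of 10: kept (boundary)

  # random windows equal a direct letter-count oracle on both strands
  set.seed(77)
  for (i in 1:100) {
    seq <- paste(sample(c("A", "C", "G", "T"), 60, TRUE), collapse = "")
    gg <- chr_genome(seq)
    st <- sample(c("+", "-"), 1)
    b <- 30L
    cli <- make_clusters(data.frame(
      cluster_id = "c1", chrom = "chrT",
      start = if (st == "+") 25L else b, end = if (st == "+") b else 35L,
      strand = st, total_reads = 50, pas = b))
    win <- if (st == "+") substr(seq, b + 1, b + 10) else
      chartr("ACGT", "TGCA", paste(rev(strsplit(substr(seq, b - 10, b - 1),
                                                "")[[1]]), collapse = ""))
    n_a <- sum(strsplit(win, "")[[1]] == "A")
    expect_equal(unname(filter_a_content(cli, gg)), n_a > 7)
  }
})

test_that("hexamer filter requires strict containment and records identity", {
  #            1234567890123456789012
  g <- chr_genome("GGGGAATAAAGGGGGGGGGGGG")
  inside <- make_clusters(data.frame(
    cluster_id = "c1", chrom = "chrT", start = 3L, end = 12L,
    strand = "+", total_reads = 50, pas = 10L))
  straddle <- make_clusters(data.frame(
    cluster_id = "c1", chrom = "chrT", start = 7L, end = 16L,
    strand = "+", total_reads = 50, pas = 10L))
  hi <- filter_hexamer(inside, g)
  expect_false(hi$hexamer_fail)
  expect_equal(hi$hexamer_found, "AAUAAA")
  hs <- filter_hexamer(straddle, g)   # starts 2 nt before the cluster
  expect_true(hs$hexamer_fail)

  # AUUAAA accepted too; absence removed
  g2 <- chr_genome("GGGGATTAAAGGGGGGGGGGGG")
  h2 <- filter_hexamer(inside, g2)
  expect_equal(h2$hexamer_found, "AUUAAA")
  g3 <- chr_genome(strrep("G", 22))
  expect_true(filter_hexamer(inside, g3)$hexamer_fail)

  # minus-strand: sense AATAAA = reference TTTATT
  gm <- chr_genome("GGGGTTTATTGGGGGGGGGGGG")
  im <- make_clusters(data.frame(
    cluster_id = "c1", chrom = "chrT", start = 3L, end = 12L,
    strand = "-", total_reads = 50, pas = 10L))
  expect_equal(filter_hexamer(im, gm)$hexamer_found, "AAUAAA")
})

test_that("reference filter is same-strand overlap; empty reference warns", {
  cl <- make_clusters(data.frame(
    cluster_id = c("c1", "c2"), chrom = "chrT", start = c(10L, 100L),
    end = c(20L, 120L), strand = "+", total_reads = c(50, 50),
    pas = c(15L, 110L)))
  ref <- GenomicRanges::GRanges("chrT", IRanges::IRanges(20, 25),
                                strand = "+")  # 1-nt overlap with c1
  flags <- filter_reference(cl, ref)
  expect_identical(unname(flags), c(FALSE, TRUE))
  # same interval, opposite strand: no overlap
  GenomicRanges::strand(ref) <- "-"
  expect_identical(unname(filter_reference(cl, ref)), c(TRUE, TRUE))
  expect_warning(filter_reference(cl, GenomicRanges::GRanges()), "empty")
})

test_that("the filter battery is order-independent", {
  sim <- simulate_genome(tiny_config())
  ends <- simulate_endseq(sim, sim_manifest())
  cl <- call_clusters(ends)
  ref <- reference_pas(sim)
  flags <- list(
    a = filter_a_run(cl, sim$genome),
    b = filter_a_content(cl, sim$genome),
    c = filter_hexamer(cl, sim$genome)$hexamer_fail,
    d = filter_reference(cl, ref))
  surviving_ref <- !(flags$a | flags$b | flags$c | flags$d)
  for (perm in list(c("d", "c", "b", "a"), c("b", "d", "a", "c"))) {
    acc <- rep(FALSE, nrow(cl$clusters))
    for (f in perm) acc <- acc | flags[[f]]
    expect_identical(!acc, surviving_ref)
  }
  expect_identical(filter_clusters(cl, sim$genome, ref)$clusters$surviving,
                   surviving_ref)
})
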