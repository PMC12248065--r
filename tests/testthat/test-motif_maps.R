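# Sliding-window motif maps, GC profiles, spacing distributions and
# reverse-complement proximity.

test_that("running mean conserves the mean and handles edges by shrinking", {
  x <- c(1, 0, 0, 4, 2, 0, 1, 3)
  for (span in c(1, 3, 5, 10)) {
    sm <- running_mean(x, span)
    expect_length(sm, length(x))
  }
  expect_equal(running_mean(x, 1), x)
  expect_equal(running_mean(x, 3)[2], mean(x[1:3]))
  expect_equal(running_mean(x, 3)[1], mean(x[1:2]))   # shrink-to-valid
  # interior smoothing of a long constant vector is exact
  expect_equal(running_mean(rep(2, 50), 7), rep(2, 50))
})

test_that("motif maps flag the sliding window containing a planted start", {
  # UGUA planted to start exactly 50 nt left of the center of a 201-mer
  seqs <- vapply(1:20, function(i) {
    s <- strrep("C", 201)
    substr(s, 51, 54) <- "TGTA"      # center at 101 -> start at rel -50
    s
  }, character(1))
  spec <- spec_ugua()
  prof <- motif_frequency_map(seqs, spec)
  hot <- prof$raw[prof$position >= -55 & prof$position <= -46]
  expect_equal(hot, rep(1, 10))      # the 10-nt window containing the start
  expect_equal(sum(prof$raw), 10)    # nothing anywhere else
  # absent motif: all zero
  none <- motif_frequency_map(rep(strrep("C", 201), 5), spec)
  expect_true(all(none$value == 0))
  # window 1, no smoothing: exact per-position indicator average
  spec1 <- motif_spec("UGUA", "UGUA", window = 4, smooth = 1)
  spec1$window <- 1L
  prof1 <- motif_frequency_map(seqs, spec1)
  expect_equal(prof1$value[prof1$position == -50], 1)
  expect_equal(sum(prof1$value), 1)
})

test_that("motif maps equal a brute-force scan oracle on random sequences", {
  set.seed(23)
  L <- 120L
  seqs <- vapply(1:30, function(i) {
    paste(sample(c("A", "C", "G", "T"), L, TRUE), collapse = "")
  }, character(1))
  spec <- motif_spec("hex", c("AAUAAA", "AUUAAA"), window = 20, smooth = 1)
  prof <- motif_frequency_map(seqs, spec)
  h1 <- (20 - 1) %/% 2
  h2 <- 20 - 1 - h1
  for (i in seq(1, L, by = 11)) {
    frac <- mean(vapply(seqs, function(s) {
      any(vapply(max(1, i - h1):min(L, i + h2), function(st) {
        substr(s, st, st + 5) %in% c("AATAAA", "ATTAAA")
      }, logical(1)))
    }, logical(1)))
    expect_equal(prof$raw[i], frac)
  }
  # smoothing conserves the overall mean up to edge shrinkage
  sm <- running_mean(prof$raw, 5)
  expect_equal(mean(sm[3:(L - 2)]), mean(prof$raw[1:L]),
               tolerance = 0.05)
})

test_that("GC profiles read composition column-wise", {
  expect_equal(gc_profile(rep(strrep("G", 50), 4))$value, rep(1, 50))
  mix <- c(strrep("G", 40), strrep("C", 40), strrep("A", 40),
           strrep("T", 40))
  expect_equal(gc_profile(mix)$value, rep(0.5, 40))
  # planted GC-rich block is elevated only there before smoothing
  seqs <- vapply(1:10, function(i) {
    left <- paste(sample(c("A", "T"), 30, TRUE), collapse = "")
    mid <- paste(sample(c("G", "C"), 20, TRUE), collapse = "")
    right <- paste(sample(c("A", "T"), 30, TRUE), collapse = "")
    paste0(left, mid, right)
  }, character(1))
  prof <- gc_profile(seqs)
  expect_true(all(prof$raw[31:50] == 1))
  expect_true(all(prof$raw[c(1:30, 51:80)] == 0))
})

test_that("spacing distances are end-to-start gaps with censoring", {
  g <- chr_genome(paste0(strrep("C", 100), "TGTA", strrep("C", 50),
                         "AATAAA", strrep("C", 200)))
  anchor <- GenomicRanges::GRanges("chrT", IRanges::IRanges(160, width = 1),
                                   strand = "+")
  sp <- motif_spacing_cdf(g, anchor, search = 150)
  expect_equal(sp$distances$distance, 50)
  expect_equal(sp$n_censored, 0)
  # no UGUA in range: censored
  g2 <- chr_genome(paste0(strrep("C", 154), "AATAAA", strrep("C", 200)))
  sp2 <- motif_spacing_cdf(g2, anchor, search = 150)
  expect_equal(nrow(sp2$distances), 0)
  expect_equal(sp2$n_censored, 1)
  # the CDF of a planted 120-nt gap steps at 120: nothing below 60
  g3 <- chr_genome(paste0(strrep("C", 30), "TGTA", strrep("C", 120),
                          "AATAAA", strrep("C", 200)))
  anchor3 <- GenomicRanges::GRanges("chrT", IRanges::IRanges(165, width = 1),
                                    strand = "+")
  sp3 <- motif_spacing_cdf(g3, anchor3, search = 150)
  cdf <- spacing_ecdf(sp3)
  expect_equal(cdf(60), 0)
  expect_equal(cdf(120), 1)
})

test_that("spacing anchors can be gated on proximal peak centers", {
  g <- chr_genome(paste0(strrep("C", 100), "TGTA", strrep("C", 50),
                         "AATAAA", strrep("C", 300)))
  anchors <- GenomicRanges::GRanges(
    "chrT", IRanges::IRanges(c(160, 400), width = 1), strand = "+")
  peaks <- GenomicRanges::GRanges("chrT", IRanges::IRanges(140, 180),
                                  strand = "+")
  sp <- motif_spacing_cdf(g, anchors, peaks = peaks, proximal = 100)
  # only the first anchor has a peak center within 100 nt
  expect_equal(nrow(sp$distances) + sp$n_censored, 1)
})

test_that("reverse-complement proximity matches the worked example", {
  # AATAAA starting at rel -29, TTTATT at rel -9 around a + anchor at
  # 200: gap = (-9) - (-24) - 1 = 14 (end-to-start)
  s <- strrep("C", 400)
  substr(s, 171, 176) <- "AATAAA"
  substr(s, 191, 196) <- "TTTATT"
  g <- chr_genome(s)
  anchor <- GenomicRanges::GRanges("chrT", IRanges::IRanges(200, width = 1),
                                   strand = "+")
  rp <- revcomp_proximity(g, anchor, spec = spec_hexamer(), search = 100)
  expect_equal(rp$spacing$distances$distance, 14)
  # pure-C background with no complement: censored
  rp0 <- revcomp_proximity(chr_genome(strrep("C", 400)), anchor,
                           search = 100)
  expect_equal(rp0$spacing$n_censored, 1)
  # the positional maps see each class at its planted position
  expect_gt(rp$sense_map$raw[rp$sense_map$position == -29], 0.99)
  expect_gt(rp$revcomp_map$raw[rp$revcomp_map$position == -9], 0.99)
})
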