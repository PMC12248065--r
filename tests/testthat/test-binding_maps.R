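# RNA maps, positional Fisher enrichment, binding fractions, feature
# priorities and Jaccard overlap.

test_that("rna_map recovers exact planted coverage windows", {
  # every anchor has one peak spanning exactly [-50, -40]
  apos <- seq(1000, 10000, by = 1000)
  anchors <- GenomicRanges::GRanges("chrT", IRanges::IRanges(apos, width = 1),
                                    strand = "+")
  peaks <- GenomicRanges::GRanges("chrT",
                                  IRanges::IRanges(apos - 50, apos - 40),
                                  strand = "+")
  prof <- rna_map(peaks, anchors, window = c(100, 100),
                  min_anchor_reads = NULL)
  expect_equal(prof$value[prof$position >= -50 & prof$position <= -40],
               rep(1, 11))
  expect_equal(sum(prof$value), 11)       # zero elsewhere
  # zero peaks: all-zero profile
  empty <- rna_map(GenomicRanges::GRanges(), anchors, window = c(100, 100),
                   min_anchor_reads = NULL)
  expect_true(all(empty$value == 0))
})

test_that("rna_map equals a per-position brute-force overlap oracle", {
  set.seed(13)
  apos <- sample(2000:8000, 25)
  astr <- sample(c("+", "-"), 25, replace = TRUE)
  anchors <- GenomicRanges::GRanges("chrT", IRanges::IRanges(apos, width = 1),
                                    strand = astr)
  pk <- random_intervals(60, max_pos = 9000, max_width = 60)
  peaks <- df_gr(pk)
  up <- 80L; down <- 40L
  prof <- rna_map(peaks, anchors, window = c(up, down),
                  min_anchor_reads = NULL)
  for (rel in seq(-up, down, by = 7)) {
    bound <- vapply(seq_along(apos), function(i) {
      gpos <- if (astr[i] == "-") apos[i] - rel else apos[i] + rel
      any(pk$chrom == "chrT" & pk$strand == astr[i] &
            pk$start <= gpos & pk$end >= gpos)
    }, logical(1))
    expect_equal(prof$value[prof$position == rel], mean(bound))
  }
})

test_that("rna_map is invariant to splitting peaks into abutting pieces", {
  anchors <- GenomicRanges::GRanges("chrT", IRanges::IRanges(500, width = 1),
                                    strand = "+")
  whole <- GenomicRanges::GRanges("chrT", IRanges::IRanges(450, 520),
                                  strand = "+")
  split_ <- GenomicRanges::GRanges("chrT",
                                   IRanges::IRanges(c(450, 481), c(480, 520)),
                                   strand = "+")
  p1 <- rna_map(whole, anchors, window = c(100, 100), min_anchor_reads = NULL)
  p2 <- rna_map(split_, anchors, window = c(100, 100), min_anchor_reads = NULL)
  expect_equal(p1$value, p2$value)
})

test_that("positional Fisher p-values match hand-checked hypergeometric tails", {
  # 10/100 regulated vs 5/200 control
  expect_equal(oracle_fisher_p(10, 90, 5, 195),
               stats::fisher.test(matrix(c(10, 90, 5, 195), 2,
                                         byrow = TRUE))$p.value,
               tolerance = 1e-12)
  # all bound vs none bound, n = 20 each: p = 2 / C(40, 20)
  expect_equal(oracle_fisher_p(20, 0, 0, 20), 2 / choose(40, 20),
               tolerance = 1e-12)
  # identical fractions: p = 1
  expect_equal(oracle_fisher_p(5, 5, 5, 5), 1, tolerance = 1e-12)
})

test_that("positional_fisher computes signed two-tailed profiles with p=1 at empty positions", {
  # 4 regulated anchors all bound at rel 0 by a 1-nt peak; 4 control unbound
  rpos <- seq(1000, 4000, by = 1000)
  cpos <- seq(11000, 14000, by = 1000)
  reg <- GenomicRanges::GRanges("chrT", IRanges::IRanges(rpos, width = 1),
                                strand = "+")
  ctl <- GenomicRanges::GRanges("chrT", IRanges::IRanges(cpos, width = 1),
                                strand = "+")
  peaks <- GenomicRanges::GRanges("chrT", IRanges::IRanges(rpos, width = 1),
                                  strand = "+")
  fi <- positional_fisher(peaks, reg, ctl, window = c(5, 5))
  at0 <- fi[fi$position == 0, ]
  expect_equal(at0$bound_regulated, 4)
  expect_equal(at0$p, oracle_fisher_p(4, 0, 0, 4), tolerance = 1e-12)
  expect_gt(at0$signed_neglog10p, 0)
  expect_true(all(fi$p[fi$position != 0] == 1))
  # empty or overlapping sets are rejected
  expect_error(positional_fisher(peaks, reg[0], ctl), "non-empty")
  expect_error(positional_fisher(peaks, reg, reg), "disjoint")
})

test_that("binding fractions respect the TPM filter and overlap oracle", {
  set.seed(17)
  utr_df <- random_intervals(30, max_pos = 4000, max_width = 150)
  utrs <- df_gr(utr_df)
  utrs$gene_id <- paste0("g", 1:30)
  pk_df <- random_intervals(40, max_pos = 4200, max_width = 60)
  peaks <- df_gr(pk_df)
  # no TPM filter: fraction equals the quadratic oracle
  res <- binding_fraction_3utr(peaks, utrs)
  expect_equal(res$fraction, mean(oracle_overlap(pk_df, utr_df)))
  # TPM filter: only expressed UTRs (median over controls >= 1) count
  tpm <- data.frame(gene_id = utrs$gene_id,
                    c1 = c(rep(5, 10), rep(0.2, 20)),
                    c2 = c(rep(4, 10), rep(0.1, 20)))
  res2 <- binding_fraction_3utr(peaks, utrs, tpm = tpm)
  expect_equal(res2$n_expressed, 10)
  expect_equal(res2$fraction,
               mean(oracle_overlap(pk_df, utr_df[1:10, ])))
  # extremes
  everything <- GenomicRanges::GRanges("chrT", IRanges::IRanges(1, 5000),
                                       strand = "+")
  plus_only <- utrs[GenomicRanges::strand(utrs) == "+"]
  expect_equal(binding_fraction_3utr(everything, plus_only)$fraction, 1)
  none <- suppressWarnings(
    binding_fraction_3utr(GenomicRanges::GRanges(), utrs))
  expect_equal(none$fraction, 0)
})

test_that("peak feature assignment follows the documented priority", {
  span <- GenomicRanges::GRanges("chrT", IRanges::IRanges(1, 1000),
                                 strand = "+")
  span$gene_id <- "g1"
  feats <- GenomicRanges::GRanges(
    "chrT", IRanges::IRanges(c(1, 1, 601, 901), c(600, 600, 900, 1000)),
    strand = "+")
  feats$gene_id <- "g1"
  feats$type <- c("terminal_exon", "cds", "utr3", "downstream_flank")
  models <- gene_models(span, feats)
  peaks <- GenomicRanges::GRanges(
    "chrT", IRanges::IRanges(c(550, 100, 950, 5000), c(650, 150, 980, 5100)),
    strand = "+")
  res <- peak_feature_fractions(peaks, models)
  # CDS+3'UTR straddler resolves to 3'UTR; pure CDS stays CDS;
  # flank peak is flank; far peak is other
  expect_equal(res$class, c("utr3", "cds", "downstream_flank", "other"))
  expect_equal(sum(res$fractions), 1)
})

test_that("base-pair Jaccard matches closed-form cases and strandedness", {
  a <- GenomicRanges::GRanges("chrT", IRanges::IRanges(1, 100), strand = "+")
  b <- GenomicRanges::GRanges("chrT", IRanges::IRanges(51, 150), strand = "+")
  expect_equal(jaccard_overlap(a, a), 1)
  expect_equal(jaccard_overlap(a, b), 50 / 150)
  bm <- b
  GenomicRanges::strand(bm) <- "-"
  expect_equal(jaccard_overlap(a, bm), 0)   # opposite strands never overlap
  far <- GenomicRanges::GRanges("chrT", IRanges::IRanges(900, 999),
                                strand = "+")
  expect_equal(jaccard_overlap(a, far), 0)
})
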