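# Independent brute-force oracles and small fixture builders used across
# the suite. Oracles deliberately share no code with the implementation.

# position-by-position scan for cluster calling on one coverage vector
oracle_clusters <- function(cov, min_per_base = 10, min_total = 20) {
  res <- list()
  i <- 1L
  n <- length(cov)
  while (i <= n) {
    if (cov[i] > min_per_base) {
      j <- i
      while (j < n && cov[j + 1L] > min_per_base) j <- j + 1L
      tot <- sum(cov[i:j])
      if (tot >= min_total) res[[length(res) + 1L]] <- c(i, j, tot)
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  if (!length(res)) {
    return(data.frame(start = integer(), end = integer(), total = numeric()))
  }
  m <- do.call(rbind, res)
  data.frame(start = m[, 1], end = m[, 2], total = m[, 3])
}

# full-enumeration two-tailed Fisher p for a 2x2 table with entries
# (a, b) / (c, d): sums all hypergeometric outcomes with probability not
# exceeding the observed one (fixed margins)
oracle_fisher_p <- function(a, b, c, d) {
  m <- a + b
  n_ <- c + d
  k <- a + c
  support <- max(0L, k - n_):min(k, m)
  probs <- stats::dhyper(support, m, n_, k)
  p_obs <- stats::dhyper(a, m, n_, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# quadratic all-pairs stranded overlap scan
oracle_overlap <- function(q_df, s_df) {
  bound <- logical(nrow(s_df))
  for (i in seq_len(nrow(s_df))) {
    for (j in seq_len(nrow(q_df))) {
      if (q_df$chrom[j] == s_df$chrom[i] &&
          q_df$strand[j] == s_df$strand[i] &&
          q_df$start[j] <= s_df$end[i] &&
          q_df$end[j] >= s_df$start[i]) {
        bound[i] <- TRUE
        break
      }
    }
  }
  bound
}

# GRanges from a plain data.frame(chrom, start, end, strand)
df_gr <- function(df) {
  GenomicRanges::GRanges(df$chrom,
                         IRanges::IRanges(df$start, df$end),
                         strand = df$strand)
}

# random stranded interval data.frame on one chromosome
random_intervals <- function(n, max_pos = 5000, max_width = 80) {
  s <- sample.int(max_pos, n, replace = TRUE)
  data.frame(chrom = "chrT", start = s,
             end = s + sample.int(max_width, n, replace = TRUE) - 1L,
             strand = sample(c("+", "-"), n, replace = TRUE))
}

# hand-built end_clusters object (the package's own S3 layout)
make_clusters <- function(df, samples = "s1",
                          counts = NULL) {
  if (is.null(counts)) {
    counts <- matrix(df$total_reads, nrow(df), length(samples),
                     dimnames = list(df$cluster_id, samples))
  }
  structure(list(clusters = df, counts = counts, samples = samples),
            class = "end_clusters")
}

# one-chromosome genome from a character string
chr_genome <- function(seq, name = "chrT") {
  Biostrings::DNAStringSet(stats::setNames(seq, name))
}

# small default simulation config used by several tests
tiny_config <- function(...) {
  args <- utils::modifyList(list(n_genes = 20, rng_seed = 421), list(...))
  do.call(sim_config, args)
}
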