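# Motif scanning and positional motif architecture: sliding-window motif
# frequency maps, UGUA<->hexamer spacing CDFs, reverse-complement
# proximity, GC-content profiles.

#' Define a motif specification
#'
#' Motifs are declared in the RNA alphabet and transliterated to DNA for
#' scanning. Defaults follow the field's conventions for short
#' cis-elements: a 10-nt sliding window for 4-mers (UGUA class) and a
#' 20-nt window for 6-mers (PAS hexamer class), with running-mean
#' smoothing over 5 nt for motif maps.
#'
#' @param name label.
#' @param kmers character vector of equal-length k-mers (RNA or DNA
#'   alphabet).
#' @param window sliding-window width in nt (defaults: 10 for 4-mers,
#'   20 for 6-mers).
#' @param smooth running-mean span for profile smoothing.
#' @return a `motif_spec` list with sense and reverse-complement DNA
#'   k-mers.
#' @export
motif_spec <- function(name, kmers, window = NULL, smooth = 5) {
  kmers <- toupper(rna_to_dna(kmers))
  k <- unique(nchar(kmers))
  if (length(k) != 1L) stop("all k-mers in a motif_spec must share a length")
  if (is.null(window)) window <- if (k <= 4) 10L else 20L
  if (window < k) stop("window must be at least the k-mer length")
  structure(list(name = name, kmers = kmers, k = k,
                 revcomp = revcomp_chr(kmers),
                 window = as.integer(window), smooth = as.integer(smooth)),
            class = "motif_spec")
}

#' Built-in motif specifications
#'
#' `spec_ugua()`: the CFIm upstream enhancer UGUA (4-mer, 10-nt window).
#' `spec_hexamer()`: the top two PAS hexamers AAUAAA/AUUAAA (6-mers,
#' 20-nt window). `spec_hexamer_rc()`: the hexamer reverse-complement
#' class as conventionally printed (UUUAUU).
#'
#' @return a [motif_spec].
#' @export
spec_ugua <- function() motif_spec("UGUA", "UGUA")

#' @rdname spec_ugua
#' @export
spec_hexamer <- function() motif_spec("PAS_hexamer", c("AAUAAA", "AUUAAA"))

#' @rdname spec_ugua
#' @export
spec_hexamer_rc <- function() motif_spec("PAS_hexamer_rc", "UUUAUU")

#' Sliding-window motif frequency map
#'
#' For equal-length sequences centered on an anchor, reports per
#' position the fraction of sequences with at least one motif occurrence
#' starting within the sliding window centered at that position
#' (window width `spec$window`; for even widths the window is
#' left-heavy), followed by running-mean smoothing over `spec$smooth`
#' positions. With `window = 1` and `smooth = 1` this is the exact
#' per-position occurrence-indicator average.
#'
#' @param seqs character vector or DNAStringSet of equal-length
#'   sense-oriented sequences (see [anchor_windows]).
#' @param spec a [motif_spec].
#' @param use_revcomp scan the reverse-complement k-mers instead of the
#'   sense k-mers.
#' @param center 1-based index of the anchor position within the
#'   sequences (defaults to the middle).
#' @return a `positional_profile` with `value` (smoothed), `raw`
#'   (pre-smoothing) and `position` relative to the anchor.
#' @export
motif_frequency_map <- function(seqs, spec, use_revcomp = FALSE,
                                center = NULL) {
  seqs <- as.character(seqs)
  stopifnot(length(unique(nchar(seqs))) == 1L)
  L <- nchar(seqs[1])
  if (is.null(center)) center <- (L + 1L) %/% 2L
  kmers <- if (use_revcomp) spec$revcomp else spec$kmers
  w <- spec$window
  h1 <- (w - 1L) %/% 2L   # window centered at i: [i - h1, i + (w - 1 - h1)]
  h2 <- w - 1L - h1
  n <- length(seqs)
  diffarr <- integer(L + 1L)
  for (s in seqs) {
    st <- kmer_starts(s, kmers)
    if (!length(st)) next
    # occurrence at `st` is inside windows centered at [st - h2, st + h1]
    ir <- IRanges::reduce(IRanges(pmax(1L, st - h2), pmin(L, st + h1)))
    diffarr[start(ir)] <- diffarr[start(ir)] + 1L
    diffarr[end(ir) + 1L] <- diffarr[end(ir) + 1L] - 1L
  }
  raw <- cumsum(diffarr[seq_len(L)]) / max(n, 1L)
  structure(list(position = seq_len(L) - center,
                 value = running_mean(raw, spec$smooth),
                 raw = raw,
                 n_anchors = n,
                 anchor_type = "motif_window"),
            class = "positional_profile")
}

#' GC-content profile across aligned sequences
#'
#' Per-position G+C fraction across equal-length sequences, smoothed
#' with a running mean (span 10 by convention for nucleotide-content
#' profiles).
#'
#' @param seqs character vector or DNAStringSet of equal-length
#'   sequences.
#' @param smooth_span running-mean span in nt.
#' @param center 1-based anchor index (defaults to the middle).
#' @return a `positional_profile` with `value` (smoothed) and `raw`.
#' @export
gc_profile <- function(seqs, smooth_span = 10, center = NULL) {
  dss <- if (is(seqs, "DNAStringSet")) seqs else DNAStringSet(seqs)
  stopifnot(length(unique(width(dss))) == 1L)
  L <- width(dss)[1]
  if (is.null(center)) center <- (L + 1L) %/% 2L
  cm <- Biostrings::consensusMatrix(dss)[c("A", "C", "G", "T"), ,
                                         drop = FALSE]
  raw <- as.numeric((cm["G", ] + cm["C", ]) / colSums(cm))
  structure(list(position = seq_len(L) - center,
                 value = running_mean(raw, smooth_span),
                 raw = raw,
                 n_anchors = length(dss),
                 anchor_type = "sequence_window"),
            class = "positional_profile")
}

# minimum gap between an occurrence of motif a (upstream) and motif b
# (downstream): gap = b_start - a_end - 1, 0 = abutting; ties broken
# towards the pair whose downstream motif is closest to `center`.
.min_gap <- function(a_starts, ka, b_starts, center = NULL) {
  if (!length(a_starts) || !length(b_starts)) return(NA_integer_)
  grid <- expand.grid(a = a_starts, b = b_starts)
  gap <- grid$b - (grid$a + ka - 1L) - 1L
  ok <- gap >= 0L
  if (!any(ok)) return(NA_integer_)
  grid <- grid[ok, ]; gap <- gap[ok]
  best <- which(gap == min(gap))
  if (length(best) > 1L && !is.null(center)) {
    best <- best[which.min(abs(grid$b[best] - center))]
  }
  gap[best[1]]
}

#' Spacing distribution between two motif classes around anchors
#'
#' For each anchor (optionally restricted to anchors with a proximal
#' peak center within `proximal` nt), scans the +/- `search` nt window
#' and records the minimum gap in nt between the 3' end of an upstream
#' `motif_a` occurrence and the 5' start of a downstream `motif_b`
#' occurrence (0 = abutting; pairs are strictly ordered a-before-b).
#' Anchors lacking such a pair are censored and counted.
#'
#' @param genome named DNAStringSet.
#' @param anchors width-1 GRanges (e.g. PAS).
#' @param motif_a,motif_b [motif_spec]s; `motif_a` is the upstream class
#'   (e.g. UGUA), `motif_b` the downstream class (e.g. the hexamer).
#' @param search half-window in nt around each anchor.
#' @param peaks optional [peak_set]/GRanges; when given, anchors are
#'   kept only if some same-strand peak center lies within `proximal`
#'   nt.
#' @param proximal proximity bound in nt for the peak filter.
#' @return a `spacing_distribution`: list with `distances` (data.frame
#'   `anchor`, `distance`), `n_censored`, `search`.
#' @export
motif_spacing_cdf <- function(genome, anchors, motif_a = spec_ugua(),
                              motif_b = spec_hexamer(), search = 150,
                              peaks = NULL, proximal = 100) {
  if (!is.null(peaks)) {
    centers <- peak_centers(peaks)
    near <- GRanges(seqnames(anchors),
                    IRanges(start(anchors) - proximal,
                            start(anchors) + proximal),
                    strand = strand(anchors))
    anchors <- anchors[overlapsAny(near, centers, ignore.strand = FALSE)]
  }
  win <- anchor_windows(genome, anchors, search, search)
  center <- search + 1L
  res <- vapply(win$seqs, function(s) {
    .min_gap(kmer_starts(s, motif_a$kmers), motif_a$k,
             kmer_starts(s, motif_b$kmers), center = center)
  }, integer(1), USE.NAMES = FALSE)
  ok <- !is.na(res)
  ids <- which(win$kept)[ok]
  structure(list(distances = data.frame(anchor = ids, distance = res[ok]),
                 n_censored = sum(!ok) + sum(!win$kept),
                 n_anchors = length(win$seqs),
                 search = search),
            class = "spacing_distribution")
}

#' @export
print.spacing_distribution <- function(x, ...) {
  cat("spacing_distribution:", nrow(x$distances), "anchors with a pair,",
      x$n_censored, "censored (search +/-", x$search, "nt)\n")
  if (nrow(x$distances)) {
    print(summary(x$distances$distance))
  }
  invisible(x)
}

#' Empirical CDF of a spacing distribution
#' @param x a `spacing_distribution`.
#' @return an [stats::ecdf] function (NULL when no distances).
#' @export
spacing_ecdf <- function(x) {
  stopifnot(inherits(x, "spacing_distribution"))
  if (!nrow(x$distances)) return(NULL)
  ecdf(x$distances$distance)
}

#' Proximity between a motif and its reverse complement
#'
#' For each anchor, scans the +/- `search` nt window for sense and
#' reverse-complement occurrences of the motif and records the minimum
#' non-negative gap between any sense/reverse-complement pair (either
#' order; gap = downstream start - upstream end - 1). Anchors lacking a
#' pair are censored. Also returns the per-position frequency maps of
#' the sense and reverse-complement occurrences.
#'
#' @param genome named DNAStringSet.
#' @param anchors width-1 GRanges.
#' @param spec a [motif_spec]; its `revcomp` k-mers are used for the
#'   complementary class.
#' @param search half-window in nt.
#' @return list: `spacing` (a `spacing_distribution`), `sense_map` and
#'   `revcomp_map` (positional profiles).
#' @export
revcomp_proximity <- function(genome, anchors, spec = spec_hexamer(),
                              search = 150) {
  win <- anchor_windows(genome, anchors, search, search)
  center <- search + 1L
  res <- vapply(win$seqs, function(s) {
    fs <- kmer_starts(s, spec$kmers)
    rs <- kmer_starts(s, spec$revcomp)
    g1 <- .min_gap(fs, spec$k, rs, center = center)
    g2 <- .min_gap(rs, spec$k, fs, center = center)
    m <- suppressWarnings(min(c(g1, g2), na.rm = TRUE))
    if (is.infinite(m)) NA_integer_ else as.integer(m)
  }, integer(1), USE.NAMES = FALSE)
  ok <- !is.na(res)
  ids <- which(win$kept)[ok]
  spacing <- structure(
    list(distances = data.frame(anchor = ids, distance = res[ok]),
         n_censored = sum(!ok) + sum(!win$kept),
         n_anchors = length(win$seqs),
         search = search),
    class = "spacing_distribution")
  list(spacing = spacing,
       sense_map = motif_frequency_map(win$seqs, spec, center = center),
       revcomp_map = motif_frequency_map(win$seqs, spec,
                                         use_revcomp = TRUE,
                                         center = center))
}
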