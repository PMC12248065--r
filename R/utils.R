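# Small shared numeric/sequence helpers.

#' Running mean with shrink-to-valid edges
#'
#' Smooths a numeric vector with a running mean of `span` positions. At the
#' edges the window shrinks to the available positions, so the output has
#' the same length as the input and the overall mean is conserved up to
#' edge effects. For even spans the window is right-heavy
#' (`floor((span-1)/2)` positions left of the focal position).
#'
#' @param x numeric vector.
#' @param span window span in positions (>= 1).
#' @return numeric vector, same length as `x`.
#' @export
running_mean <- function(x, span) {
  stopifnot(is.numeric(x), span >= 1)
  span <- as.integer(span)
  if (span == 1L || length(x) == 0L) return(x)
  n <- length(x)
  h1 <- (span - 1L) %/% 2L
  h2 <- span - 1L - h1
  cs <- cumsum(c(0, x))
  i <- seq_len(n)
  lo <- pmax(1L, i - h1)
  hi <- pmin(n, i + h2)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Extract a sense-strand genomic sequence
#'
#' Returns the sequence of `[start, end]` (1-based closed) on `chrom`,
#' reverse-complemented when `strand == "-"` so the result always reads
#' 5'->3' in transcript orientation. Coordinates beyond the contig are
#' clamped; a fully out-of-range request returns "".
#'
#' @param genome a named [Biostrings::DNAStringSet].
#' @param chrom,start,end,strand locus to extract.
#' @return a character scalar.
#' @export
get_seq <- function(genome, chrom, start, end, strand = "+") {
  stopifnot(chrom %in% names(genome))
  len <- length(genome[[chrom]])
  s <- max(1L, as.integer(start))
  e <- min(len, as.integer(end))
  if (s > e) return("")
  out <- subseq(genome[[chrom]], s, e)
  if (strand == "-") out <- reverseComplement(out)
  as.character(out)
}

# longest run of `letter` in a character scalar
longest_run <- function(seq_chr, letter = "A") {
  if (!nzchar(seq_chr)) return(0L)
  m <- gregexpr(paste0(letter, "+"), seq_chr)[[1]]
  if (m[1] == -1L) return(0L)
  max(attr(m, "match.length"))
}

# count of `letter` in a character scalar
count_letter <- function(seq_chr, letter = "A") {
  if (!nzchar(seq_chr)) return(0L)
  lengths(regmatches(seq_chr, gregexpr(letter, seq_chr, fixed = TRUE)))
}

#' Sense-oriented sequence windows around anchors
#'
#' Extracts, for each single-nucleotide anchor, the window from `up`
#' nucleotides upstream to `down` nucleotides downstream in transcript
#' orientation (minus-strand windows are reverse-complemented). Anchors
#' whose window runs off the contig are dropped with a warning.
#'
#' @param genome named [Biostrings::DNAStringSet].
#' @param anchors width-1 [GenomicRanges::GRanges] of anchor positions.
#' @param up,down window extent in nt; the window has `up + down + 1`
#'   positions labelled `-up .. down` with the anchor at 0.
#' @return list with `seqs` (character vector), `rel` (relative position
#'   labels) and `kept` (logical, which anchors were in range).
#' @export
anchor_windows <- function(genome, anchors, up, down) {
  stopifnot(all(width(anchors) == 1L))
  chroms <- as.character(seqnames(anchors))
  strands <- as.character(strand(anchors))
  pos <- start(anchors)
  lo <- ifelse(strands == "-", pos - down, pos - up)
  hi <- ifelse(strands == "-", pos + up, pos + down)
  lens <- vapply(chroms, function(ch) length(genome[[ch]]), integer(1))
  kept <- lo >= 1L & hi <= lens
  if (!all(kept)) {
    warning(sum(!kept), " anchor(s) dropped: window exceeds contig bounds")
  }
  seqs <- character(sum(kept))
  idx <- which(kept)
  for (j in seq_along(idx)) {
    i <- idx[j]
    seqs[j] <- get_seq(genome, chroms[i], lo[i], hi[i], strands[i])
  }
  list(seqs = seqs, rel = seq.int(-up, down), kept = kept)
}

# transliterate an RNA-alphabet motif to DNA
rna_to_dna <- function(x) chartr("Uu", "Tt", x)

# reverse complement of DNA k-mers (character)
revcomp_chr <- function(x) {
  vapply(x, function(k) as.character(reverseComplement(DNAString(k))),
         character(1), USE.NAMES = FALSE)
}

# all start positions of any of `kmers` in `seq_chr` (1-based), sorted unique
kmer_starts <- function(seq_chr, kmers) {
  out <- integer(0)
  for (k in kmers) {
    m <- gregexpr(k, seq_chr, fixed = TRUE)[[1]]
    if (m[1] != -1L) out <- c(out, as.integer(m))
  }
  sort(unique(out))
}
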