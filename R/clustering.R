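# 3'-end read cluster calling, PAS assignment, and the four-filter
# battery against internal priming and spurious sites.

#' Cluster a pooled per-base coverage vector
#'
#' Low-level cluster definition on one coverage vector: a cluster is a
#' maximal run of consecutive positions each with coverage strictly
#' greater than `min_per_base`; candidate clusters with total coverage
#' below `min_cluster_reads` are removed.
#'
#' @param cov integer vector of pooled per-base read 3'-end counts.
#' @param min_per_base per-position threshold (strict: a position needs
#'   more than this many pooled reads).
#' @param min_cluster_reads minimum total pooled reads per retained
#'   cluster (clusters with fewer are removed).
#' @return data.frame with 1-based `start`, `end` indices and `total`.
#' @export
cluster_coverage <- function(cov, min_per_base = 10, min_cluster_reads = 20) {
  keep <- cov > min_per_base
  if (!any(keep)) {
    return(data.frame(start = integer(), end = integer(), total = numeric()))
  }
  r <- rle(keep)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  cs <- cumsum(c(0, cov))
  total <- cs[ends[runs] + 1L] - cs[starts[runs]]
  out <- data.frame(start = starts[runs], end = ends[runs], total = total)
  out[out$total >= min_cluster_reads, , drop = FALSE]
}

#' Assign the PAS of a cluster
#'
#' The PAS is the single nucleotide with the highest pooled coverage in
#' the cluster; ties are broken towards the transcript 3' end (highest
#' coordinate on "+", lowest on "-").
#'
#' @param positions integer positions within the cluster.
#' @param counts pooled coverage at each position.
#' @param strand "+" or "-".
#' @return the PAS position.
#' @export
assign_pas <- function(positions, counts, strand = "+") {
  stopifnot(length(positions) == length(counts), length(positions) > 0)
  top <- which(counts == max(counts))
  cand <- positions[top]
  if (strand == "+") max(cand) else min(cand)
}

#' Call 3'-end clusters from multi-sample read termini
#'
#' Pools read 3'-end positions across all samples, merges runs of
#' consecutive positions with pooled coverage strictly greater than
#' `min_per_base` per strand and chromosome, removes clusters with fewer
#' than `min_cluster_reads` pooled reads, and assigns each cluster its
#' PAS (coverage argmax, 3'-most on ties).
#'
#' @param ends data.table/data.frame of single-nucleotide 3' ends with
#'   columns `chrom`, `pos`, `strand`, `sample_id` (see
#'   [read_ends_bed], [simulate_endseq]).
#' @param min_per_base,min_cluster_reads see [cluster_coverage].
#' @param samples sample ids defining the count-matrix columns (defaults
#'   to the samples present in `ends`).
#' @return an `end_clusters` object: `clusters` (data.frame with
#'   `cluster_id`, `chrom`, `start`, `end`, `strand`, `total_reads`,
#'   `pas`) and `counts` (cluster x sample matrix of per-sample reads).
#' @export
call_clusters <- function(ends, min_per_base = 10, min_cluster_reads = 20,
                          samples = NULL) {
  ends <- as.data.table(ends)
  if (is.null(samples)) samples <- sort(unique(ends$sample_id))
  empty <- function() {
    structure(list(
      clusters = data.frame(cluster_id = character(), chrom = character(),
                            start = integer(), end = integer(),
                            strand = character(), total_reads = numeric(),
                            pas = integer()),
      counts = matrix(0, 0, length(samples),
                      dimnames = list(NULL, samples)),
      samples = samples), class = "end_clusters")
  }
  if (nrow(ends) == 0L) return(empty())
  pooled <- ends[, .N, by = .(chrom, strand, pos)]
  pooled <- pooled[N > min_per_base]
  if (nrow(pooled) == 0L) return(empty())
  setorder(pooled, chrom, strand, pos)
  pooled[, grp := cumsum(c(1L, as.integer(
    diff(pos) != 1L |
      chrom[-1] != chrom[-.N] |
      strand[-1] != strand[-.N])))]
  cl <- pooled[, .(chrom = chrom[1], strand = strand[1],
                   start = min(pos), end = max(pos),
                   total_reads = sum(N),
                   pas = assign_pas(pos, N, strand[1])),
               by = grp]
  cl <- cl[total_reads >= min_cluster_reads]
  if (nrow(cl) == 0L) return(empty())
  setorder(cl, chrom, start)
  cl[, cluster_id := sprintf("cl%04d", seq_len(.N))]
  # per-sample counts of reads falling inside each cluster (interval join)
  counts <- matrix(0L, nrow(cl), length(samples),
                   dimnames = list(cl$cluster_id, samples))
  reads <- copy(ends)[, c("start", "end") := .(pos, pos)]
  cldt <- cl[, .(chrom, strand, start, end, cluster_id)]
  setkey(cldt, chrom, strand, start, end)
  ov <- data.table::foverlaps(reads, cldt,
                              by.x = c("chrom", "strand", "start", "end"),
                              nomatch = NULL)
  if (nrow(ov)) {
    tab <- ov[, .N, by = .(cluster_id, sample_id)]
    counts[cbind(match(tab$cluster_id, cl$cluster_id),
                 match(tab$sample_id, samples))] <- tab$N
  }
  clusters <- as.data.frame(cl[, .(cluster_id, chrom, start, end, strand,
                                   total_reads, pas)])
  structure(list(clusters = clusters, counts = counts, samples = samples),
            class = "end_clusters")
}

#' @export
print.end_clusters <- function(x, ...) {
  cat("end_clusters:", nrow(x$clusters), "clusters,",
      length(x$samples), "samples\n")
  if (!is.null(x$clusters$surviving)) {
    cat("  surviving after filters:", sum(x$clusters$surviving), "\n")
  }
  invisible(x)
}

# sequence immediately 3' of `pos` in transcript orientation
.downstream_seq <- function(genome, chrom, pos, strand, window) {
  if (strand == "+") get_seq(genome, chrom, pos + 1L, pos + window, "+")
  else get_seq(genome, chrom, pos - window, pos - 1L, "-")
}

#' Internal-priming and signal filters for end clusters
#'
#' The four-filter battery applied to called clusters:
#' \describe{
#'   \item{`filter_a_run`}{flags clusters with a run of more than
#'     `max_run` consecutive genomically encoded adenosines (sense
#'     strand) within `window` nt directly downstream of the PAS.}
#'   \item{`filter_a_content`}{flags clusters with more than `max_a` A's
#'     in the `window` nt directly downstream of the cluster's 3'
#'     boundary.}
#'   \item{`filter_hexamer`}{keeps clusters containing one of the top
#'     two PAS hexamers (AAUAAA or AUUAAA; DNA sense AATAAA/ATTAAA)
#'     fully within the cluster interval; records which.}
#'   \item{`filter_reference`}{keeps clusters overlapping at least one
#'     reference PAS record (PolyA_DB-like BED) on the same strand.}
#' }
#' Each `filter_*` returns a logical flag per cluster, `TRUE` = fails
#' (cluster removed). PAS at contig edges are inspected over whatever
#' sequence exists.
#'
#' @param clusters an `end_clusters` object.
#' @param genome named [Biostrings::DNAStringSet].
#' @param max_run maximum allowed downstream A-run length (strict).
#' @param window inspection window in nt.
#' @name cluster_filters
NULL

#' @rdname cluster_filters
#' @export
filter_a_run <- function(clusters, genome, max_run = 6, window = 10) {
  cl <- clusters$clusters
  vapply(seq_len(nrow(cl)), function(i) {
    s <- .downstream_seq(genome, cl$chrom[i], cl$pas[i], cl$strand[i], window)
    longest_run(s, "A") > max_run
  }, logical(1))
}

#' @rdname cluster_filters
#' @param max_a maximum allowed A count in the window (strict).
#' @export
filter_a_content <- function(clusters, genome, window = 10, max_a = 7) {
  cl <- clusters$clusters
  vapply(seq_len(nrow(cl)), function(i) {
    boundary <- if (cl$strand[i] == "+") cl$end[i] else cl$start[i]
    s <- .downstream_seq(genome, cl$chrom[i], boundary, cl$strand[i], window)
    count_letter(s, "A") > max_a
  }, logical(1))
}

#' @rdname cluster_filters
#' @export
filter_hexamer <- function(clusters, genome) {
  cl <- clusters$clusters
  hex <- character(nrow(cl))
  fail <- logical(nrow(cl))
  for (i in seq_len(nrow(cl))) {
    s <- get_seq(genome, cl$chrom[i], cl$start[i], cl$end[i], cl$strand[i])
    if (grepl("AATAAA", s, fixed = TRUE)) {
      hex[i] <- "AAUAAA"
    } else if (grepl("ATTAAA", s, fixed = TRUE)) {
      hex[i] <- "AUUAAA"
    } else {
      hex[i] <- "none"
      fail[i] <- TRUE
    }
  }
  data.frame(hexamer_fail = fail, hexamer_found = hex,
             stringsAsFactors = FALSE)
}

#' @rdname cluster_filters
#' @param reference GRanges of reference PAS records.
#' @export
filter_reference <- function(clusters, reference) {
  cl <- clusters$clusters
  if (length(reference) == 0L) {
    warning("empty reference PAS set: all clusters fail the reference filter")
    return(rep(TRUE, nrow(cl)))
  }
  gr <- GRanges(cl$chrom, IRanges(cl$start, cl$end), strand = cl$strand)
  !overlapsAny(gr, reference, ignore.strand = FALSE)
}

#' Apply the full filter battery
#'
#' Runs all four filters (order-independent) and annotates the cluster
#' table with the individual flags, the hexamer identity and a
#' `surviving` column (all flags FALSE).
#'
#' @inheritParams cluster_filters
#' @param reference GRanges of reference PAS records.
#' @param max_run,a_window,max_a,run_window filter parameters; see
#'   [cluster_filters].
#' @return the `end_clusters` object with filter columns added.
#' @export
filter_clusters <- function(clusters, genome, reference,
                            max_run = 6, run_window = 10,
                            a_window = 10, max_a = 7) {
  cl <- clusters$clusters
  cl$a_run_fail <- filter_a_run(clusters, genome, max_run, run_window)
  cl$a_content_fail <- filter_a_content(clusters, genome, a_window, max_a)
  hx <- filter_hexamer(clusters, genome)
  cl$hexamer_fail <- hx$hexamer_fail
  cl$hexamer_found <- hx$hexamer_found
  cl$reference_fail <- filter_reference(clusters, reference)
  cl$surviving <- !(cl$a_run_fail | cl$a_content_fail |
                      cl$hexamer_fail | cl$reference_fail)
  clusters$clusters <- cl
  clusters
}

#' Subset an `end_clusters` object to surviving clusters
#' @param clusters a filtered `end_clusters` object.
#' @return an `end_clusters` object with only surviving clusters.
#' @export
surviving_clusters <- function(clusters) {
  stopifnot(!is.null(clusters$clusters$surviving))
  keep <- clusters$clusters$surviving
  clusters$clusters <- clusters$clusters[keep, , drop = FALSE]
  clusters$counts <- clusters$counts[keep, , drop = FALSE]
  clusters
}
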