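# Stranded CLIP peak sets and peak/feature intersection.

#' Construct a PeakSet
#'
#' A `peak_set` wraps the stranded peak intervals of one CLIP experiment
#' with its confidence tier. Tier `"any"` denotes the union of peaks from
#' either replicate (binding-evidence analyses); `"reproducible"` denotes
#' a single high-confidence (e.g. IDR) peak file. IDR itself is never
#' computed here.
#'
#' @param peaks [GenomicRanges::GRanges] of stranded peaks; an optional
#'   `peak` metadata column carries the summit offset (narrowPeak
#'   convention, -1 when absent).
#' @param experiment_id,cell_context identifiers.
#' @param tier `"any"` or `"reproducible"`.
#' @return an object of class `peak_set`.
#' @export
peak_set <- function(peaks, experiment_id = "exp", cell_context = "cell",
                     tier = c("any", "reproducible")) {
  tier <- match.arg(tier)
  stopifnot(is(peaks, "GRanges"))
  if (any(as.character(strand(peaks)) == "*")) {
    stop("peak_set requires stranded peaks (eCLIP is stranded)")
  }
  peaks <- GenomicRanges::sort(peaks)
  structure(list(peaks = peaks, experiment_id = experiment_id,
                 cell_context = cell_context, tier = tier),
            class = "peak_set")
}

#' @export
print.peak_set <- function(x, ...) {
  cat("peak_set", x$experiment_id, "(", x$cell_context, ", tier:", x$tier,
      "):", length(x$peaks), "peaks\n")
  invisible(x)
}

# accept peak_set or bare GRanges
.peaks_gr <- function(x) {
  if (inherits(x, "peak_set")) x$peaks else x
}

# peak centers: narrowPeak summit when present (>= 0), else midpoint
peak_centers <- function(peaks) {
  gr <- .peaks_gr(peaks)
  mid <- as.integer(floor((start(gr) + end(gr)) / 2))
  if (!is.null(gr$peak)) {
    has_summit <- !is.na(gr$peak) & gr$peak >= 0L
    mid[has_summit] <- start(gr)[has_summit] + gr$peak[has_summit]
  }
  GRanges(seqnames(gr), IRanges(mid, width = 1L), strand = strand(gr))
}

#' Intersect peaks with features
#'
#' A feature counts as bound iff at least one peak overlaps it by >= 1 nt
#' on the same strand (eCLIP is stranded). Also returns the per-peak
#' assignment of all overlapped features.
#'
#' @param peaks a `peak_set` or GRanges.
#' @param features GRanges of features.
#' @return list with `bound` (logical per feature) and `assignment`
#'   (data.frame of peak/feature index pairs).
#' @export
intersect_peaks <- function(peaks, features) {
  gr <- .peaks_gr(peaks)
  pc <- unique(as.character(seqnames(gr)))
  fc <- unique(as.character(seqnames(features)))
  unmatched <- c(setdiff(pc, fc), setdiff(fc, pc))
  if (length(unmatched)) {
    warning("chromosome name(s) present in only one input: ",
            paste(unmatched, collapse = ", "))
  }
  hits <- findOverlaps(gr, features, ignore.strand = FALSE)
  bound <- logical(length(features))
  bound[unique(subjectHits(hits))] <- TRUE
  list(bound = bound,
       assignment = data.frame(peak = queryHits(hits),
                               feature = subjectHits(hits)))
}
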