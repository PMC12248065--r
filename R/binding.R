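# eCLIP positional analytics: binding fractions, feature assignment,
# per-nucleotide RNA maps, positional Fisher enrichment, Jaccard overlap.

#' Fraction of expressed 3'UTRs with binding evidence
#'
#' Filters 3'UTRs to those of expressed transcripts (median TPM across
#' control columns at or above `tpm_threshold`) and reports the fraction
#' overlapped by at least one same-strand peak. Intended for tier
#' `"any"` peak sets (union of replicate peaks).
#'
#' @param peaks a [peak_set] or GRanges.
#' @param utrs GRanges of 3'UTRs; metadata column `gene_id` (or `name`)
#'   links to the expression table.
#' @param tpm data.frame whose first column is the gene/transcript id
#'   and remaining columns are per-sample TPM; `NULL` skips the filter.
#' @param tpm_threshold expression threshold on the median TPM.
#' @return list: `fraction`, `n_expressed`, `n_bound`, `bound` (logical
#'   per retained UTR).
#' @export
binding_fraction_3utr <- function(peaks, utrs, tpm = NULL,
                                  tpm_threshold = 1) {
  ids <- if (!is.null(utrs$gene_id)) utrs$gene_id else utrs$name
  if (!is.null(tpm)) {
    med <- apply(as.matrix(tpm[, -1, drop = FALSE]), 1, median)
    expressed_ids <- tpm[[1]][med >= tpm_threshold]
    utrs <- utrs[ids %in% expressed_ids]
  }
  if (length(utrs) == 0L) {
    return(list(fraction = NA_real_, n_expressed = 0L, n_bound = 0L,
                bound = logical(0)))
  }
  bound <- intersect_peaks(peaks, utrs)$bound
  list(fraction = mean(bound), n_expressed = length(utrs),
       n_bound = sum(bound), bound = bound)
}

#' Assign peaks to transcript feature classes
#'
#' Each peak is assigned to exactly one feature class by priority
#' (default: 3'UTR > 5'UTR > CDS > non-coding exon > intron >
#' downstream flank > other); fractions over all peaks sum to 1.
#' Introns are derived as gene-span minus exonic features.
#'
#' @param peaks a [peak_set] (tier `reproducible` intended) or GRanges.
#' @param models a [gene_models] object.
#' @param priority character vector of feature classes, highest first.
#' @return list: `fractions` (named, sums to 1), `class` (per peak).
#' @export
peak_feature_fractions <- function(peaks, models,
                                   priority = c("utr3", "utr5", "cds",
                                                "noncoding_exon", "intron",
                                                "downstream_flank")) {
  gr <- .peaks_gr(peaks)
  feats <- models$features
  nonintron <- feats[feats$type %in% c("terminal_exon", "utr3", "utr5",
                                       "cds", "noncoding_exon",
                                       "downstream_flank")]
  introns <- GenomicRanges::setdiff(models$span, nonintron,
                                    ignore.strand = FALSE)
  if (length(introns)) {
    introns$gene_id <- NA_character_
    introns$type <- "intron"
  }
  all_feats <- c(feats, introns)
  cls <- rep("other", length(gr))
  for (type in rev(priority)) {
    f <- all_feats[all_feats$type == type]
    if (length(f) == 0L) next
    hit <- overlapsAny(gr, f, ignore.strand = FALSE)
    cls[hit] <- type
  }
  lev <- c(priority, "other")
  fr <- table(factor(cls, levels = lev)) / length(gr)
  list(fractions = as.numeric(fr) |> setNames(lev), class = cls)
}

# per-anchor per-relative-position bound indicator counts.
# Returns integer vector over rel positions -up..down: number of anchors
# covered by >= 1 same-strand peak at that transcript-relative position.
.positional_counts <- function(peaks_gr, anchors, up, down) {
  n_pos <- up + down + 1L
  counts <- integer(n_pos)
  if (length(anchors) == 0L || length(peaks_gr) == 0L) return(counts)
  win <- GRanges(seqnames(anchors),
                 IRanges(start(anchors) - ifelse(strand(anchors) == "-",
                                                 down, up),
                         start(anchors) + ifelse(strand(anchors) == "-",
                                                 up, down)),
                 strand = strand(anchors))
  hits <- findOverlaps(win, peaks_gr, ignore.strand = FALSE)
  if (length(hits) == 0L) return(counts)
  qa <- queryHits(hits); sp <- subjectHits(hits)
  apos <- start(anchors)[qa]
  minus <- as.character(strand(anchors))[qa] == "-"
  # transcript-relative covered interval, clipped to the window
  rs <- ifelse(minus, apos - end(peaks_gr)[sp], start(peaks_gr)[sp] - apos)
  re <- ifelse(minus, apos - start(peaks_gr)[sp], end(peaks_gr)[sp] - apos)
  rs <- pmax(rs, -up); re <- pmin(re, down)
  ok <- rs <= re
  qa <- qa[ok]; rs <- rs[ok]; re <- re[ok]
  # per anchor: union of covered intervals, then accumulate via diff array
  diffarr <- integer(n_pos + 1L)
  for (a in unique(qa)) {
    sel <- qa == a
    ir <- IRanges::reduce(IRanges(rs[sel] + up + 1L, re[sel] + up + 1L))
    diffarr[start(ir)] <- diffarr[start(ir)] + 1L
    diffarr[end(ir) + 1L] <- diffarr[end(ir) + 1L] - 1L
  }
  cumsum(diffarr[seq_len(n_pos)])
}

#' Per-nucleotide RNA map of binding around anchors
#'
#' For each transcript-relative position in `[-window[1], window[2]]`
#' (anchor at 0, orientation flipped for minus-strand anchors), reports
#' the fraction of anchors covered there by at least one same-strand
#' peak. Anchors may be pre-filtered by read support (`reads` metadata
#' column, e.g. 3'-end read counts), mirroring the "highly expressed
#' PAS" filter.
#'
#' @param peaks a [peak_set] or GRanges.
#' @param anchors width-1 GRanges (e.g. PAS); optional `reads` column.
#' @param window `c(upstream, downstream)` in nt.
#' @param min_anchor_reads drop anchors with fewer reads (`NULL` =
#'   keep all; ignored when `anchors` has no `reads` column).
#' @return a `positional_profile`: list with `position`
#'   (-up..down), `value` (fraction in [0, 1]), `counts`, `n_anchors`,
#'   `anchor_type`.
#' @export
rna_map <- function(peaks, anchors, window = c(500, 500),
                    min_anchor_reads = 100) {
  gr <- .peaks_gr(peaks)
  if (!is.null(min_anchor_reads) && !is.null(anchors$reads)) {
    anchors <- anchors[anchors$reads >= min_anchor_reads]
  }
  up <- as.integer(window[1]); down <- as.integer(window[2])
  counts <- .positional_counts(gr, anchors, up, down)
  structure(list(position = seq.int(-up, down),
                 value = if (length(anchors)) counts / length(anchors)
                         else rep(0, up + down + 1L),
                 counts = counts,
                 n_anchors = length(anchors),
                 anchor_type = "pas"),
            class = "positional_profile")
}

#' @export
print.positional_profile <- function(x, ...) {
  cat("positional_profile:", length(x$position), "positions,",
      x$n_anchors, "anchors; max value",
      signif(max(x$value), 3), "at position",
      x$position[which.max(x$value)], "\n")
  invisible(x)
}

#' Convert a positional profile to a data.frame
#' @param x a `positional_profile`.
#' @param ... unused.
#' @export
as.data.frame.positional_profile <- function(x, ...) {
  data.frame(position = x$position, value = x$value,
             n = x$n_anchors)
}

#' Two-tailed Fisher exact p for one bound/unbound 2x2 table
#'
#' The per-position test behind [positional_fisher]: for `bound_a` of
#' `n_a` anchors bound in one set and `bound_b` of `n_b` in the other,
#' the two-tailed exact p is the sum of all conditional (fixed-margin)
#' table probabilities not exceeding the observed table's.
#'
#' @param bound_a,n_a bound count and set size of the first anchor set.
#' @param bound_b,n_b bound count and set size of the second.
#' @return p-value in (0, 1].
#' @export
fisher_exact_2x2 <- function(bound_a, n_a, bound_b, n_b) {
  stats::fisher.test(matrix(c(bound_a, n_a - bound_a,
                              bound_b, n_b - bound_b),
                            nrow = 2))$p.value
}

#' Positional Fisher-exact enrichment between two PAS sets
#'
#' At each transcript-relative position, counts anchors with same-strand
#' peak coverage in the regulated and in the control set, forms the 2x2
#' table [bound, unbound] x [regulated, control] and computes the
#' two-tailed Fisher exact p-value (sum of all conditional table
#' probabilities not exceeding the observed table's). The reported
#' signed significance is -log10(p), positive where the regulated
#' bound-fraction exceeds the control one. Positions with no binding in
#' either set have p = 1. No multiple-testing correction is applied by
#' default (profiles are plotted as raw -log10 p); `adjust = "BH"`
#' applies Benjamini-Hochberg across positions.
#'
#' @param peaks a [peak_set] or GRanges.
#' @param regulated,control disjoint width-1 GRanges anchor sets.
#' @param window `c(upstream, downstream)` in nt.
#' @param adjust `"none"` or `"BH"`.
#' @return an `enrichment_row`: data.frame with `position`,
#'   `bound_regulated`, `bound_control`, `p`, `signed_neglog10p`, plus
#'   attributes `n_regulated`, `n_control`.
#' @export
positional_fisher <- function(peaks, regulated, control,
                              window = c(500, 500),
                              adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  if (length(regulated) == 0L || length(control) == 0L) {
    stop("regulated and control anchor sets must both be non-empty")
  }
  if (length(GenomicRanges::intersect(granges(regulated),
                                      granges(control)))) {
    stop("regulated and control anchor sets must be disjoint")
  }
  gr <- .peaks_gr(peaks)
  up <- as.integer(window[1]); down <- as.integer(window[2])
  b_reg <- .positional_counts(gr, regulated, up, down)
  b_ctl <- .positional_counts(gr, control, up, down)
  n_reg <- length(regulated); n_ctl <- length(control)
  cache <- new.env(parent = emptyenv())
  pvals <- vapply(seq_along(b_reg), function(i) {
    key <- paste(b_reg[i], b_ctl[i])
    if (!is.null(cache[[key]])) return(cache[[key]])
    p <- fisher_exact_2x2(b_reg[i], n_reg, b_ctl[i], n_ctl)
    cache[[key]] <- p
    p
  }, numeric(1))
  if (adjust == "BH") pvals <- p.adjust(pvals, "BH")
  sgn <- sign(b_reg / n_reg - b_ctl / n_ctl)
  out <- data.frame(position = seq.int(-up, down),
                    bound_regulated = b_reg,
                    bound_control = b_ctl,
                    p = pvals,
                    signed_neglog10p = sgn * -log10(pmax(pvals, 1e-300)))
  attr(out, "n_regulated") <- n_reg
  attr(out, "n_control") <- n_ctl
  class(out) <- c("enrichment_row", class(out))
  out
}

#' Base-pair Jaccard index between two peak sets
#'
#' Jaccard = |intersection| / |union| in covered base pairs over merged
#' stranded intervals.
#'
#' @param peaks_a,peaks_b [peak_set]s or GRanges.
#' @return Jaccard index in [0, 1] (1 when both sets are empty is
#'   undefined and returned as NA).
#' @export
jaccard_overlap <- function(peaks_a, peaks_b) {
  a <- GenomicRanges::reduce(granges(.peaks_gr(peaks_a)))
  b <- GenomicRanges::reduce(granges(.peaks_gr(peaks_b)))
  un <- sum(width(GenomicRanges::union(a, b)))
  if (un == 0) return(NA_real_)
  inter <- sum(width(GenomicRanges::intersect(a, b)))
  inter / un
}
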