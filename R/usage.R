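# Per-terminal-exon relative PAS usage, replicate-consistent change
# calling, and nuclear/cytoplasmic compartment comparison.

#' Assign surviving clusters to terminal exons
#'
#' A cluster belongs to a terminal exon iff its PAS position falls inside
#' the exon, optionally extended downstream by `flank` nt in transcript
#' orientation (3'-end clusters can extend slightly past annotated ends).
#' Clusters matching no terminal exon get `NA`.
#'
#' @param clusters an `end_clusters` object.
#' @param models a [gene_models] object.
#' @param flank downstream extension in nt allowed beyond the annotated
#'   terminal exon.
#' @return the `end_clusters` object with an `exon_id` column added.
#' @export
assign_to_exons <- function(clusters, models, flank = 0) {
  cl <- clusters$clusters
  te <- gene_features(models, "terminal_exon")
  if (flank > 0) {
    plus <- as.character(strand(te)) == "+"
    end(te)[plus] <- end(te)[plus] + as.integer(flank)
    start(te)[!plus] <- pmax(1L, start(te)[!plus] - as.integer(flank))
  }
  pas_gr <- GRanges(cl$chrom, IRanges(cl$pas, width = 1L),
                    strand = cl$strand)
  hits <- findOverlaps(pas_gr, te, ignore.strand = FALSE, select = "first")
  cl$exon_id <- ifelse(is.na(hits), NA_character_, te$gene_id[hits])
  clusters$clusters <- cl
  clusters
}

#' Compute per-sample relative PAS usage per terminal exon
#'
#' Usage of a cluster in a sample is its read count over the summed reads
#' of all clusters assigned to the same terminal exon in that sample.
#' Samples in which the exon has zero reads get `NA` usage (flagged, not
#' 0/0). Clusters are ordered 5'->3' in transcript orientation within
#' each exon (`rank_tx`; the highest rank is the distal PAS).
#'
#' @param clusters an `end_clusters` object with `exon_id` assigned (see
#'   [assign_to_exons]); clusters without an exon are dropped.
#' @return a `usage_table`: data.table with one row per
#'   (exon, cluster, sample): `exon_id`, `cluster_id`, `rank_tx`, `pas`,
#'   `sample_id`, `count`, `exon_total`, `usage`.
#' @export
compute_usage <- function(clusters) {
  cl <- clusters$clusters
  stopifnot(!is.null(cl$exon_id))
  keep <- !is.na(cl$exon_id)
  cl <- cl[keep, , drop = FALSE]
  counts <- clusters$counts[keep, , drop = FALSE]
  long <- data.table(
    exon_id = rep(cl$exon_id, ncol(counts)),
    cluster_id = rep(cl$cluster_id, ncol(counts)),
    pas = rep(cl$pas, ncol(counts)),
    strand = rep(cl$strand, ncol(counts)),
    sample_id = rep(colnames(counts), each = nrow(counts)),
    count = as.vector(counts))
  # 5'->3' rank in transcript orientation
  long[, rank_tx := if (strand[1] == "+") frank(pas, ties.method = "dense")
       else frank(-pas, ties.method = "dense"),
       by = .(exon_id, sample_id)]
  long[, exon_total := sum(count), by = .(exon_id, sample_id)]
  long[, usage := ifelse(exon_total > 0, count / exon_total, NA_real_)]
  setorder(long, exon_id, rank_tx, sample_id)
  structure(long, class = c("usage_table", class(long)))
}

#' Per-replicate usage deltas (knockdown minus control)
#'
#' Pairs knockdown and control samples by (compartment, replicate) from
#' the manifest and computes, per cluster, the usage difference
#' delta = usage(kd) - usage(control) for each matched pair.
#'
#' @param usage a `usage_table` from [compute_usage].
#' @param manifest manifest data.frame (see [read_manifest]); the
#'   condition labelled `control` is the baseline, every other condition
#'   label is treated as knockdown.
#' @param control name of the control condition.
#' @return data.table with `exon_id`, `cluster_id`, `rank_tx`,
#'   `compartment`, `replicate`, `delta`, `total_kd`, `total_ctrl`.
#' @export
usage_deltas <- function(usage, manifest, control = "control") {
  m <- as.data.table(manifest)
  if (is.null(m$compartment)) m[, compartment := "whole_cell"]
  u <- merge(as.data.table(usage), m, by = "sample_id")
  ctrl <- u[condition == control]
  kd <- u[condition != control]
  merged <- merge(
    kd[, .(exon_id, cluster_id, rank_tx, compartment, replicate,
           usage_kd = usage, total_kd = exon_total)],
    ctrl[, .(exon_id, cluster_id, rank_tx, compartment, replicate,
             usage_ctrl = usage, total_ctrl = exon_total)],
    by = c("exon_id", "cluster_id", "rank_tx", "compartment", "replicate"))
  merged[, delta := usage_kd - usage_ctrl]
  merged[]
}

# change call for one cluster's replicate deltas:
# >= need_n of them with |delta| >= min_delta and a common sign, and no
# delta of the opposite sign (any magnitude); zeros are neutral.
.cluster_change <- function(deltas, min_delta, need_n) {
  d <- deltas[!is.na(deltas)]
  if (length(d) == 0L) return("none")
  up <- sum(d >= min_delta)
  dn <- sum(d <= -min_delta)
  if (up >= need_n && all(d >= 0)) return("up")
  if (dn >= need_n && all(d <= 0)) return("down")
  "none"
}

#' Call changing terminal exons (replicate-consistency rule)
#'
#' A PAS cluster is called changing iff at least `ceiling(2k/3)` of its
#' `k` replicate deltas reach `min_delta` in absolute value with a common
#' sign and no replicate moved in the opposite direction (any
#' magnitude). An exon is changing iff at least one of its clusters is
#' changing; its direction (3'UTR `lengthening` vs `shortening` upon
#' knockdown) is the sign of the distal cluster's delta. Exons with a
#' missing replicate pair or fewer than two clusters cannot be called
#' changing.
#'
#' @param deltas data.table from [usage_deltas] (one compartment).
#' @param min_delta minimum absolute usage change (fraction).
#' @param n_replicates expected replicate pairs; default inferred.
#' @return list with `clusters` (per-cluster calls) and `exons`
#'   (per-exon: `exon_id`, `changing`, `direction`, `n_clusters`,
#'   `complete`).
#' @export
call_changes <- function(deltas, min_delta = 0.10, n_replicates = NULL) {
  d <- as.data.table(deltas)
  if (is.null(n_replicates)) n_replicates <- length(unique(d$replicate))
  need_n <- ceiling(2 * n_replicates / 3)
  cl <- d[, .(
    n_pairs = sum(!is.na(delta)),
    direction = .cluster_change(delta, min_delta, need_n),
    rank_tx = rank_tx[1]
  ), by = .(exon_id, cluster_id)]
  cl[, changing := direction != "none" & n_pairs == n_replicates]
  ex <- cl[, .(
    n_clusters = .N,
    complete = all(n_pairs == n_replicates),
    changing = any(changing) & .N >= 2L & all(n_pairs == n_replicates)
  ), by = exon_id]
  # exon direction from the distal (highest-rank) cluster's mean delta
  distal <- d[, .SD[rank_tx == max(rank_tx)], by = exon_id][
    , .(distal_delta = mean(delta, na.rm = TRUE)), by = exon_id]
  ex <- merge(ex, distal, by = "exon_id", all.x = TRUE)
  ex[, direction := ifelse(!changing, NA_character_,
                           ifelse(distal_delta > 0, "lengthening",
                                  "shortening"))]
  list(clusters = cl[], exons = ex[])
}

#' Flag confidently non-changing terminal exons
#'
#' An exon is confidently non-changing iff it has at least `min_reads`
#' total reads in every sample and no cluster's usage changed by more
#' than `max_delta` in any replicate knockdown/control pair.
#'
#' @param usage a `usage_table`.
#' @param deltas data.table from [usage_deltas] (one compartment).
#' @param min_reads minimum per-sample exon total.
#' @param max_delta maximum tolerated |delta| in any replicate pair.
#' @return data.table: `exon_id`, `non_changing`.
#' @export
call_nonchanging <- function(usage, deltas, min_reads = 10,
                             max_delta = 0.05) {
  u <- as.data.table(usage)
  depth_ok <- u[, .(depth_ok = all(exon_total >= min_reads)), by = exon_id]
  d <- as.data.table(deltas)
  quiet <- d[, .(quiet = all(!is.na(delta)) && all(abs(delta) <= max_delta)),
             by = exon_id]
  out <- merge(depth_ok, quiet, by = "exon_id", all = TRUE)
  out[, non_changing := isTRUE(depth_ok) & isTRUE(quiet),
      by = seq_len(nrow(out))]
  out[, .(exon_id, non_changing)]
}

#' Consolidated per-exon differential call for one compartment
#'
#' Combines [call_changes] and [call_nonchanging]: an exon is
#' `changing`, else `non_changing` if confidently quiet, else
#' `indeterminate`.
#'
#' @param usage a `usage_table` restricted to one compartment's samples,
#'   or a full table plus a manifest subset.
#' @param manifest manifest rows for the samples of this compartment.
#' @param min_delta,min_reads,max_delta thresholds (see the two callers).
#' @return data.table: `exon_id`, `call`, `direction`.
#' @export
diff_usage <- function(usage, manifest, min_delta = 0.10,
                       min_reads = 10, max_delta = 0.05) {
  u <- as.data.table(usage)[sample_id %in% manifest$sample_id]
  d <- usage_deltas(u, manifest)
  ch <- call_changes(d, min_delta = min_delta,
                     n_replicates = length(unique(
                       manifest$replicate[manifest$condition != "control"])))
  nc <- call_nonchanging(u, d, min_reads = min_reads, max_delta = max_delta)
  out <- merge(ch$exons[, .(exon_id, changing, direction)], nc,
               by = "exon_id", all = TRUE)
  out[, call := ifelse(isTRUE(changing), "changing",
                       ifelse(isTRUE(non_changing), "non_changing",
                              "indeterminate")),
      by = seq_len(nrow(out))]
  out[, .(exon_id, call, direction)]
}

#' Compare differential calls between two compartments
#'
#' Shared events change in both compartments; compartment-specific
#' events change in one compartment AND are confidently non-changing in
#' the other. Exons changing in one compartment but indeterminate in the
#' other belong to no category.
#'
#' @param nuclear,cytoplasmic per-exon call tables from [diff_usage].
#' @return list of exon-id vectors: `shared`, `nuclear_specific`,
#'   `cytoplasmic_specific`.
#' @export
compare_compartments <- function(nuclear, cytoplasmic) {
  n <- as.data.table(nuclear)
  c_ <- as.data.table(cytoplasmic)
  m <- merge(n[, .(exon_id, call_nuc = call)],
             c_[, .(exon_id, call_cyt = call)],
             by = "exon_id", all = TRUE)
  m[is.na(call_nuc), call_nuc := "indeterminate"]
  m[is.na(call_cyt), call_cyt := "indeterminate"]
  list(
    shared = m[call_nuc == "changing" & call_cyt == "changing", exon_id],
    nuclear_specific = m[call_nuc == "changing" &
                           call_cyt == "non_changing", exon_id],
    cytoplasmic_specific = m[call_cyt == "changing" &
                               call_nuc == "non_changing", exon_id])
}
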