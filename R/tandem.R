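# Classification of DaPars-style dPDUI tables and a simplified two-PAS
# PDUI estimator for synthetic coverage.

#' Read a DaPars-style dPDUI table
#'
#' Tolerant reader: accepts the package's own column names (`exon_id`,
#' `gene_id`, `PDUI_ctrl`, `PDUI_kd`, `p_adj`) or common DaPars output
#' names (`Event_id`/`Gene`, `A_PDUI`/`B_PDUI` or
#' `PDUI_Group_A`/`PDUI_Group_B` group means, `adjusted.P_val`/`FDR`).
#' Group A is taken as the control.
#'
#' @param path TSV file.
#' @return data.frame with standardized columns.
#' @export
read_dpdui_table <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                   stringsAsFactors = FALSE, check.names = FALSE)
  pick <- function(cands) {
    hit <- intersect(cands, names(df))
    if (length(hit)) df[[hit[1]]] else NULL
  }
  out <- data.frame(
    exon_id = pick(c("exon_id", "Event_id", "event_id", "Loci")),
    gene_id = pick(c("gene_id", "Gene", "gene")),
    PDUI_ctrl = pick(c("PDUI_ctrl", "A_PDUI", "PDUI_Group_A",
                       "Group_A_Mean_PDUI")),
    PDUI_kd = pick(c("PDUI_kd", "B_PDUI", "PDUI_Group_B",
                     "Group_B_Mean_PDUI")),
    stringsAsFactors = FALSE)
  p <- pick(c("p_adj", "adjusted.P_val", "adjusted_P_val", "FDR", "fdr"))
  out$p_adj <- if (is.null(p)) NA_real_ else p
  if (is.null(out$exon_id) || is.null(out$PDUI_ctrl) || is.null(out$PDUI_kd)) {
    stop("could not locate exon/PDUI columns in ", path)
  }
  if (is.null(out$gene_id)) out$gene_id <- sub("\\..*$", "", out$exon_id)
  out$dPDUI <- out$PDUI_ctrl - out$PDUI_kd
  out
}

#' Classify tandem-APA calls from a dPDUI table
#'
#' dPDUI = PDUI(control) - PDUI(knockdown). Terminal exons with
#' `|dPDUI| >= delta_thresh` and adjusted p below `sig_alpha` are
#' changing: `rbp_lengthens` when dPDUI > 0 (depletion shifts usage to
#' the proximal PAS, i.e. the RBP promotes the long 3'UTR) and
#' `rbp_shortens` when dPDUI < 0. Exons with `|dPDUI| < null_delta` and
#' adjusted p above `sig_alpha` are `non_changing`; everything else
#' (including rows with missing p) is `other`.
#'
#' @param table data.frame with columns `exon_id`, `gene_id`,
#'   `PDUI_ctrl`, `PDUI_kd` and `p_adj` (or a path readable by
#'   [read_dpdui_table]).
#' @param delta_thresh minimum |dPDUI| for a changing call.
#' @param sig_alpha adjusted-p significance threshold.
#' @param null_delta maximum |dPDUI| for a non-changing call.
#' @return the table with `dPDUI` and `class` columns.
#' @export
classify_calls <- function(table, delta_thresh = 0.20, sig_alpha = 0.05,
                           null_delta = 0.05) {
  if (is.character(table)) table <- read_dpdui_table(table)
  df <- as.data.frame(table)
  stopifnot(all(c("PDUI_ctrl", "PDUI_kd") %in% names(df)))
  df$dPDUI <- df$PDUI_ctrl - df$PDUI_kd
  if (is.null(df$p_adj)) {
    warning("missing adjusted-p column: all rows classed 'other'")
    df$p_adj <- NA_real_
  }
  if (anyNA(df$p_adj)) {
    warning(sum(is.na(df$p_adj)), " row(s) with missing p_adj classed 'other'")
  }
  cls <- rep("other", nrow(df))
  ok <- !is.na(df$p_adj)
  chg <- ok & abs(df$dPDUI) >= delta_thresh & df$p_adj < sig_alpha
  cls[chg & df$dPDUI > 0] <- "rbp_lengthens"
  cls[chg & df$dPDUI < 0] <- "rbp_shortens"
  cls[ok & abs(df$dPDUI) < null_delta & df$p_adj > sig_alpha] <- "non_changing"
  df$class <- cls
  df
}

#' Summarize classified calls per RBP experiment
#'
#' Counts changing terminal exons, unique genes with at least one
#' changing exon (multi-exon genes count once), and the fractions of
#' changing exons that are lengthening vs shortening.
#'
#' @param calls data.frame from [classify_calls].
#' @param rbp_id,cell_context identifiers carried into the summary.
#' @return one-row data.frame (`rbp_summary`).
#' @export
summarize_rbp <- function(calls, rbp_id = "rbp", cell_context = "cell") {
  chg <- calls[calls$class %in% c("rbp_lengthens", "rbp_shortens"), ]
  n_chg <- nrow(chg)
  data.frame(
    rbp_id = rbp_id,
    cell_context = cell_context,
    n_changing_exons = n_chg,
    n_unique_genes = length(unique(chg$gene_id)),
    fraction_lengthening = if (n_chg) mean(chg$class == "rbp_lengthens") else NA_real_,
    fraction_shortening = if (n_chg) mean(chg$class == "rbp_shortens") else NA_real_,
    stringsAsFactors = FALSE)
}

#' Simplified two-PAS PDUI estimator from coverage
#'
#' Stands in for regression-based PDUI inference when working with
#' synthetic coverage: PDUI is the mean RNA-seq-like coverage of the
#' extended 3'UTR segment (between the proximal and distal PAS,
#' proximal-exclusive) divided by the mean coverage of the common
#' segment 5' of the proximal PAS, clamped to [0, 1].
#'
#' @param coverage per-base coverage vector over the terminal exon in
#'   transcript orientation (position 1 = 5' end).
#' @param proximal_pas,distal_pas 1-based positions within `coverage`;
#'   proximal must be 5' of distal.
#' @return PDUI fraction in [0, 1].
#' @export
estimate_pdui <- function(coverage, proximal_pas, distal_pas) {
  stopifnot(proximal_pas < distal_pas, distal_pas <= length(coverage),
            proximal_pas >= 1)
  common <- mean(coverage[seq_len(proximal_pas)])
  extended <- mean(coverage[(proximal_pas + 1L):distal_pas])
  if (common <= 0) return(0)
  min(1, max(0, extended / common))
}
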