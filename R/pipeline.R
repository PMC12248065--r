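# End-to-end synthetic pipeline driver: one config -> all declared
# outputs (genome, annotation, pileups, clusters, usage, differential
# calls, compartment overlap, RNA map, Fisher map, motif spacing).

#' Run the full synthetic APA pipeline
#'
#' Simulates a scenario (genome + annotation + multi-sample 3'-end
#' pileups + peaks + dPDUI table), then runs every analysis stage:
#' cluster calling, the internal-priming filter battery, per-exon usage,
#' per-compartment differential calls, compartment comparison, dPDUI
#' classification, the PAS-anchored RNA map, the positional Fisher
#' enrichment profile and the UGUA-hexamer spacing distribution. All
#' declared tables are written under `outdir` as TSV (plus FASTA/GTF/
#' BED/narrowPeak for the simulated inputs).
#'
#' @param config a [sim_config], or the path to a YAML file whose keys
#'   are `sim_config()` arguments.
#' @param outdir output directory (created if needed); `NULL` skips all
#'   file output.
#' @param window RNA-map / Fisher window, `c(upstream, downstream)` nt.
#' @param min_delta,min_reads,max_delta differential-usage thresholds
#'   (see [diff_usage]).
#' @return (invisibly) a list with every intermediate result.
#' @export
run_pipeline <- function(config = sim_config(), outdir = NULL,
                         window = c(500, 500), min_delta = 0.10,
                         min_reads = 10, max_delta = 0.05) {
  if (is.character(config)) {
    args <- yaml::read_yaml(config)
    config <- do.call(sim_config, args)
  }
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(outdir) && !dir.exists(outdir)) {
    dir.create(outdir, recursive = TRUE)
  }
  emit <- function(df, name, comments) {
    if (!is.null(outdir)) {
      write_tsv(df, file.path(outdir, name), comments)
    }
  }

  sim <- simulate_genome(config)
  manifest <- sim_manifest()
  ends <- simulate_endseq(sim, manifest)
  peaks <- simulate_peaks(sim)
  dpdui <- simulate_dpdui_table(sim)

  clusters <- call_clusters(ends)
  clusters <- filter_clusters(clusters, sim$genome, reference_pas(sim))
  surv <- assign_to_exons(surviving_clusters(clusters), sim$models,
                          flank = 50)
  usage <- compute_usage(surv)

  calls <- lapply(split(manifest, manifest$compartment), function(m) {
    diff_usage(usage, m, min_delta = min_delta,
               min_reads = min_reads, max_delta = max_delta)
  })
  comp <- if (all(c("nuclear", "cytoplasmic") %in% names(calls))) {
    compare_compartments(calls$nuclear, calls$cytoplasmic)
  } else NULL

  dp_calls <- classify_calls(dpdui$table)
  rbp_summary <- summarize_rbp(dp_calls, rbp_id = "sim_rbp",
                               cell_context = "sim")

  changing_genes <- sim$truth$genes$gene_id[sim$truth$genes$changing]
  null_genes <- sim$truth$genes$gene_id[!sim$truth$genes$changing]
  reg_anchors <- pas_anchors(sim, rank = 1, genes = changing_genes)
  ctl_anchors <- pas_anchors(sim, rank = 1, genes = null_genes)
  map <- rna_map(peaks, reg_anchors, window = window,
                 min_anchor_reads = NULL)
  fisher <- positional_fisher(peaks, reg_anchors, ctl_anchors,
                              window = window)
  spacing <- motif_spacing_cdf(sim$genome, reg_anchors,
                               peaks = peaks)

  if (!is.null(outdir)) {
    write_genome(sim$genome, file.path(outdir, "genome.fa"))
    write_gtf(sim$models, file.path(outdir, "annotation.gtf"))
    write_narrowpeak(peaks$peaks, file.path(outdir, "peaks.narrowPeak"))
    write_bed(reference_pas(sim), file.path(outdir, "reference_pas.bed"))
    for (s in manifest$sample_id) {
      write_ends_bed(ends[sample_id == s],
                     file.path(outdir, paste0("ends_", s, ".bed")))
    }
    emit(manifest, "manifest.tsv", "sample manifest")
    emit(clusters$clusters, "clusters.tsv",
         c("3'-end clusters, pooled over all samples",
           "filters: a_run, a_content, hexamer, reference"))
    emit(as.data.frame(usage), "usage.tsv",
         "per-exon per-sample relative PAS usage")
    for (nm in names(calls)) {
      emit(as.data.frame(calls[[nm]]),
           paste0("calls_", nm, ".tsv"),
           paste("differential usage calls,", nm, "compartment"))
    }
    if (!is.null(comp)) {
      comp_df <- data.frame(
        exon_id = unlist(comp, use.names = FALSE),
        category = rep(names(comp), lengths(comp)))
      emit(comp_df, "compartments.tsv", "compartment overlap categories")
    }
    emit(dp_calls, "dpdui_calls.tsv", "classified dPDUI table")
    emit(rbp_summary, "rbp_summary.tsv", "per-RBP summary")
    emit(as.data.frame(map), "rna_map.tsv",
         "fraction of regulated proximal PAS with peak coverage per position")
    emit(as.data.frame(fisher), "fisher_map.tsv",
         "positional two-tailed Fisher enrichment, regulated vs control PAS")
    emit(spacing$distances, "spacing.tsv",
         "minimum UGUA->hexamer gap per anchor (nt)")
  }

  invisible(list(sim = sim, manifest = manifest, ends = ends,
                 peaks = peaks, clusters = clusters, surviving = surv,
                 usage = usage, calls = calls, compartments = comp,
                 dpdui = dpdui, dpdui_calls = dp_calls,
                 rbp_summary = rbp_summary, rna_map = map,
                 fisher = fisher, spacing = spacing))
}
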