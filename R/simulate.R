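# Deterministic synthetic-data generator with planted ground truth:
# genome + annotation with planted PAS motif architecture, multi-sample
# 3'-end pileups, CLIP-like peak sets and dPDUI tables.

#' Simulation configuration
#'
#' Defines the study conditions for a synthetic two-condition (control vs
#' knockdown), two-compartment, multi-replicate 3'-end sequencing
#' scenario. Defaults emulate a targeted 3'-end sequencing experiment at
#' moderate depth with tandem (two-PAS) terminal exons, a planted usage
#' shift in half the genes, A-rich internal-priming decoys in 10% of
#' genes, and canonical polyadenylation motif geometry: the PAS hexamer
#' 10-15 nt upstream of a CA cleavage dinucleotide, the UGUA element
#' `ugua_gap` nt upstream of the hexamer, and a U/G-rich (A-free)
#' downstream sequence element after the cleavage site.
#'
#' Read 3' ends are drawn per PAS from a mixture of tight cleavage jitter
#' (triangular, max `jitter_max`) and an upstream cleavage-heterogeneity
#' tail (uniform over `-tail_span..-1`, fraction `tail_frac`), so pooled
#' clusters span the hexamer as observed cluster boundaries do in real
#' 3'-end data.
#'
#' @param n_genes number of genes.
#' @param pas_per_exon PAS per terminal exon (>= 2 for tandem APA).
#' @param depth mean reads per terminal exon per sample (Poisson).
#' @param usage_control,usage_kd per-PAS usage fractions (proximal ->
#'   distal), each summing to 1; `usage_kd` applies to planted changing
#'   genes in the affected compartment(s).
#' @param frac_changing fraction of genes with a planted usage shift.
#' @param compartment_plan named fractions (`shared`, `cytoplasmic`,
#'   `nuclear`) partitioning changing genes by where the shift occurs.
#' @param jitter_max max symmetric cleavage jitter in nt.
#' @param tail_frac,tail_span upstream heterogeneity mixture weight and
#'   span in nt.
#' @param priming_artifact_rate fraction of genes given an A-rich decoy
#'   site.
#' @param artifact_read_fraction decoy read depth relative to `depth`.
#' @param artifact_run_length length of the planted genomic A-run.
#' @param artifact_jitter max jitter at decoy sites.
#' @param hex_offset_range distance (nt) from hexamer end to cleavage
#'   site, drawn uniformly per PAS.
#' @param ugua_gap gap (nt) between UGUA end and hexamer start.
#' @param gc_background,gc_linker GC fraction of background sequence and
#'   of the UGUA-hexamer linker (`NULL` = background).
#' @param dse_length length of the planted A-free downstream element.
#' @param cds_length CDS length per gene.
#' @param peak_offset,peak_offset_spread planted peak-center offset from
#'   the proximal PAS (transcript orientation; negative = upstream) and
#'   its uniform half-spread.
#' @param peak_width planted peak width in nt.
#' @param background_peak_rate probability an unbound gene receives one
#'   background peak in its CDS.
#' @param dpdui_noise Gaussian noise SD on simulated PDUI values.
#' @param rng_seed integer seed; fixed seed gives byte-identical outputs.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_genes = 200,
                       pas_per_exon = 2,
                       depth = 500,
                       usage_control = c(0.3, 0.7),
                       usage_kd = c(0.6, 0.4),
                       frac_changing = 0.5,
                       compartment_plan = c(shared = 0.8, cytoplasmic = 0.1,
                                            nuclear = 0.1),
                       jitter_max = 5,
                       tail_frac = 0.5,
                       tail_span = 26,
                       priming_artifact_rate = 0.1,
                       artifact_read_fraction = 0.3,
                       artifact_run_length = 15,
                       artifact_jitter = 2,
                       hex_offset_range = c(10, 15),
                       ugua_gap = 50,
                       gc_background = 0.5,
                       gc_linker = NULL,
                       dse_length = 20,
                       cds_length = 200,
                       peak_offset = -50,
                       peak_offset_spread = 10,
                       peak_width = 30,
                       background_peak_rate = 0.5,
                       dpdui_noise = 0.01,
                       rng_seed = 1) {
  cfg <- as.list(environment())
  stopifnot(pas_per_exon >= 2,
            length(usage_control) == pas_per_exon,
            length(usage_kd) == pas_per_exon,
            abs(sum(usage_control) - 1) < 1e-8,
            abs(sum(usage_kd) - 1) < 1e-8,
            jitter_max >= 0, tail_frac >= 0, tail_frac <= 1,
            all(c("shared", "cytoplasmic", "nuclear") %in%
                  names(compartment_plan)),
            abs(sum(compartment_plan) - 1) < 1e-8)
  structure(cfg, class = "sim_config")
}

# background patterns never allowed outside planted elements: planted
# motifs, their reverse complements, and A-runs (>= 5).
.FORBIDDEN <- c("AATAAA", "ATTAAA", "TGTA", "TACA", "TTTATT", "AAAAA",
                "TTTTT")

# Mutate any forbidden occurrence at its middle base. The replacement is
# C (none of the patterns contains C, so a C can never create one); when
# the middle base already is C (TACA) G is used instead, which cannot
# complete any forbidden pattern in the contexts these patterns provide.
sanitize_background <- function(seq_chr) {
  ch <- strsplit(seq_chr, "", fixed = TRUE)[[1]]
  repeat {
    s <- paste(ch, collapse = "")
    hit <- FALSE
    for (p in .FORBIDDEN) {
      m <- gregexpr(p, s, fixed = TRUE)[[1]]
      if (m[1] != -1L) {
        hit <- TRUE
        at <- as.integer(m) + nchar(p) %/% 2L
        ch[at] <- ifelse(ch[at] == "C", "G", "C")
      }
    }
    if (!hit) return(paste(ch, collapse = ""))
  }
}

# random background at given GC, sanitized; first/last base forced to C
# so no forbidden pattern can span a junction between assembled pieces
# (every forbidden pattern is C-free)
.bg <- function(n, gc) {
  if (n <= 0) return("")
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  s <- sanitize_background(paste(sample(names(p), n, TRUE, prob = p),
                                 collapse = ""))
  if (n >= 2) {
    substr(s, 1L, 1L) <- "C"
    substr(s, n, n) <- "C"
  }
  s
}

# A-free U/G-rich downstream element (CstF-like DSE); G-guarded ends
# (the only G-containing forbidden pattern, TGTA, cannot straddle a
# junction whose boundary bases are G/C). T-runs are capped at 4 so the
# element is not an A-run on the opposite genomic strand.
.dse <- function(n) {
  ch <- sample(c("T", "G"), n, TRUE, prob = c(0.7, 0.3))
  r <- rle(ch)
  long <- which(r$values == "T" & r$lengths > 4L)
  if (length(long)) {
    ends <- cumsum(r$lengths)
    for (i in long) {
      run <- (ends[i] - r$lengths[i] + 1L):ends[i]
      ch[run[seq(5L, length(run), by = 5L)]] <- "G"
    }
  }
  if (n >= 2) {
    ch[1L] <- "G"
    ch[n] <- "G"
  }
  paste(ch, collapse = "")
}

#' Simulate a genome with planted PAS architecture
#'
#' Builds a single-chromosome genome of single-exon genes (half plus,
#' half minus strand). Each terminal exon carries `pas_per_exon` true PAS
#' blocks (UGUA, GC-controlled linker, AAUAAA/AUUAAA hexamer, CA cleavage
#' site, A-free DSE) and, in a configured fraction of genes, one decoy
#' internal-priming site (a genomic A-run with no hexamer). Background
#' sequence is sanitized so planted motifs occur nowhere else and
#' terminal exons contain no A-runs beyond the planted decoys.
#'
#' @param config a [sim_config].
#' @return a `apa_sim` list: `genome` (DNAStringSet), `models`
#'   ([gene_models]), `truth` (list of `genes` and `pas` data.frames) and
#'   `config`.
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$rng_seed)
  n <- config$n_genes
  k <- config$pas_per_exon
  gc <- config$gc_background
  gc_link <- if (is.null(config$gc_linker)) gc else config$gc_linker
  strands <- rep(c("+", "-"), length.out = n)
  changing <- seq_len(n) %in% sample(n, round(config$frac_changing * n))
  comp_class <- rep(NA_character_, n)
  idx_ch <- which(changing)
  if (length(idx_ch)) {
    comp_class[idx_ch] <- sample(
      names(config$compartment_plan), length(idx_ch), TRUE,
      prob = config$compartment_plan)
  }
  has_decoy <- seq_len(n) %in%
    sample(n, round(config$priming_artifact_rate * n))

  chrom <- "chrS1"
  pieces <- list()
  cursor <- 0L          # genome position of last written base
  gene_rows <- vector("list", n)
  pas_rows <- list()
  gtag <- function(i) sprintf("g%03d", i)

  for (i in seq_len(n)) {
    spacer <- .bg(600, gc)
    # --- build gene in sense coordinates ---
    gp <- list(); gpos <- 0L
    put <- function(s) {
      gp[[length(gp) + 1L]] <<- s
      gpos <<- gpos + nchar(s)
      gpos
    }
    put(.bg(config$cds_length, gc))
    cds_end_sense <- gpos
    pas_sense <- integer(k)
    hex_chosen <- character(k)
    hex_off <- integer(k)
    ugua_sense <- integer(k)
    hex_sense <- integer(k)
    for (j in seq_len(k)) {
      put(.bg(sample(30:60, 1), gc))
      ugua_sense[j] <- gpos + 1L
      put("TGTA")
      put(.bg(config$ugua_gap, gc_link))
      hex_sense[j] <- gpos + 1L
      hex_chosen[j] <- sample(c("AATAAA", "ATTAAA"), 1, prob = c(0.75, 0.25))
      put(hex_chosen[j])
      hex_end <- gpos
      off_opts <- seq.int(config$hex_offset_range[1],
                          config$hex_offset_range[2])
      hex_off[j] <- off_opts[sample.int(length(off_opts), 1)]
      put(.bg(hex_off[j] - 2L, gc))
      put("CA")
      pas_sense[j] <- gpos       # cleavage at the A of the CA dinucleotide
      stopifnot(pas_sense[j] - hex_end == hex_off[j])
      put(.dse(config$dse_length))
    }
    decoy_sense <- NA_integer_
    if (has_decoy[i]) {
      put(.bg(40, gc))
      decoy_sense <- gpos        # last base before the A-run
      put(strrep("A", config$artifact_run_length))
    }
    put(.bg(sample(40:80, 1), gc))
    gene_seq <- paste(unlist(gp), collapse = "")
    L <- nchar(gene_seq)

    st <- strands[i]
    g_start <- cursor + nchar(spacer) + 1L
    g_end <- g_start + L - 1L
    placed <- if (st == "-") {
      as.character(reverseComplement(DNAString(gene_seq)))
    } else gene_seq
    pieces[[length(pieces) + 1L]] <- spacer
    pieces[[length(pieces) + 1L]] <- placed
    cursor <- g_end

    to_abs <- function(p) if (st == "+") g_start + p - 1L else g_end - p + 1L
    gid <- gtag(i)
    gene_rows[[i]] <- data.frame(
      gene_id = gid, chrom = chrom, start = g_start, end = g_end,
      strand = st, changing = changing[i],
      compartment_class = comp_class[i], has_decoy = has_decoy[i],
      cds_end_sense = cds_end_sense, length = L,
      stringsAsFactors = FALSE)
    u_kd <- if (changing[i]) config$usage_kd else config$usage_control
    pas_rows[[length(pas_rows) + 1L]] <- data.frame(
      gene_id = gid,
      pas_id = paste0(gid, "_pas", seq_len(k)),
      rank = seq_len(k), type = "true", chrom = chrom,
      pos = vapply(pas_sense, to_abs, integer(1)), strand = st,
      hexamer = hex_chosen, hex_offset = hex_off,
      ugua_gap = config$ugua_gap,
      hex_pos = vapply(hex_sense, to_abs, integer(1)),
      ugua_pos = vapply(ugua_sense, to_abs, integer(1)),
      usage_control = config$usage_control, usage_kd = u_kd,
      stringsAsFactors = FALSE)
    if (has_decoy[i]) {
      pas_rows[[length(pas_rows) + 1L]] <- data.frame(
        gene_id = gid, pas_id = paste0(gid, "_decoy"),
        rank = NA_integer_, type = "decoy", chrom = chrom,
        pos = to_abs(decoy_sense), strand = st,
        hexamer = NA_character_, hex_offset = NA_integer_,
        ugua_gap = NA_integer_, hex_pos = NA_integer_,
        ugua_pos = NA_integer_,
        usage_control = NA_real_, usage_kd = NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  pieces[[length(pieces) + 1L]] <- .bg(600, gc)
  genome <- DNAStringSet(setNames(paste(unlist(pieces), collapse = ""), chrom))

  genes <- do.call(rbind, gene_rows)
  pas <- do.call(rbind, pas_rows)
  rownames(pas) <- NULL

  span <- GRanges(chrom, IRanges(genes$start, genes$end),
                  strand = genes$strand)
  span$gene_id <- genes$gene_id
  # single-exon transcript: terminal exon = whole span; CDS = 5' part
  te <- span; te$type <- "terminal_exon"
  plus <- genes$strand == "+"
  cds <- GRanges(chrom, IRanges(
    ifelse(plus, genes$start, genes$end - genes$cds_end_sense + 1L),
    ifelse(plus, genes$start + genes$cds_end_sense - 1L, genes$end)),
    strand = genes$strand)
  cds$gene_id <- genes$gene_id; cds$type <- "cds"
  utr <- GRanges(chrom, IRanges(
    ifelse(plus, genes$start + genes$cds_end_sense, genes$start),
    ifelse(plus, genes$end, genes$end - genes$cds_end_sense)),
    strand = genes$strand)
  utr$gene_id <- genes$gene_id; utr$type <- "utr3"
  models <- gene_models(span, c(te, cds, utr))

  structure(list(genome = genome, models = models,
                 truth = list(genes = genes, pas = pas),
                 config = config),
            class = "apa_sim")
}

#' @export
print.apa_sim <- function(x, ...) {
  cat("apa_sim:", nrow(x$truth$genes), "genes,",
      sum(x$truth$pas$type == "true"), "true PAS,",
      sum(x$truth$pas$type == "decoy"), "decoy sites\n")
  invisible(x)
}

#' Build a sample manifest for a simulated scenario
#'
#' @param replicates replicates per condition/compartment.
#' @param conditions condition labels; the first is the control.
#' @param compartments compartment labels.
#' @return data.frame with `sample_id`, `condition`, `compartment`,
#'   `replicate`.
#' @export
sim_manifest <- function(replicates = 3,
                         conditions = c("control", "kd"),
                         compartments = c("nuclear", "cytoplasmic")) {
  g <- expand.grid(replicate = seq_len(replicates),
                   condition = conditions,
                   compartment = compartments,
                   stringsAsFactors = FALSE)
  g$sample_id <- paste(g$condition, g$compartment, g$replicate, sep = "_")
  g[, c("sample_id", "condition", "compartment", "replicate")]
}

# usage vector of one gene in one (condition, compartment)
.gene_usage <- function(gene_row, config, condition, compartment) {
  if (condition == "control" || !isTRUE(gene_row$changing)) {
    return(config$usage_control)
  }
  cls <- gene_row$compartment_class
  if (is.na(cls) || cls == "shared" || cls == compartment) {
    config$usage_kd
  } else {
    config$usage_control
  }
}

# offset sampling distributions (transcript orientation)
.true_offset_dist <- function(config) {
  j <- config$jitter_max
  tri <- (j + 1) - abs(seq.int(-j, j))
  tri <- (1 - config$tail_frac) * tri / sum(tri)
  # uniform heterogeneity tail over -tail_span..-1, triangle over -j..j
  offs <- seq.int(-config$tail_span, j)
  prob <- numeric(length(offs))
  prob[offs < 0] <- prob[offs < 0] + config$tail_frac / config$tail_span
  in_tri <- offs >= -j
  prob[in_tri] <- prob[in_tri] + tri[offs[in_tri] + j + 1L]
  list(offs = offs, prob = prob / sum(prob))
}

.decoy_offset_dist <- function(config) {
  j <- config$artifact_jitter
  offs <- seq.int(-j, j)
  w <- (j + 1) - abs(offs)
  list(offs = offs, prob = w / sum(w))
}

#' Simulate 3'-end sequencing pileups
#'
#' Draws per-sample single-nucleotide read 3'-end positions: per terminal
#' exon, total reads ~ Poisson(depth), distributed over PAS by the
#' gene's usage vector for the sample's (condition, compartment), with
#' cleavage jitter and upstream heterogeneity; decoy sites receive
#' tightly-jittered reads at `artifact_read_fraction * depth`. Sampling
#' is sequential over the manifest, so replicates share a seed stream
#' but have distinct reads, and a fixed seed reproduces outputs exactly.
#'
#' @param sim an `apa_sim` from [simulate_genome].
#' @param manifest data.frame from [sim_manifest] (or compatible).
#' @param depth override of `config$depth`.
#' @return data.table of read 3' ends: `chrom`, `pos`, `strand`,
#'   `sample_id`, `origin` (planted site of origin).
#' @export
simulate_endseq <- function(sim, manifest, depth = NULL) {
  stopifnot(inherits(sim, "apa_sim"))
  config <- sim$config
  if (is.null(depth)) depth <- config$depth
  set.seed(config$rng_seed + 104729L)
  td <- .true_offset_dist(config)
  dd <- .decoy_offset_dist(config)
  genes <- sim$truth$genes
  pas <- sim$truth$pas
  true_pas <- pas[pas$type == "true", ]
  decoys <- pas[pas$type == "decoy", ]
  out <- list()
  for (si in seq_len(nrow(manifest))) {
    srow <- manifest[si, ]
    for (gi in seq_len(nrow(genes))) {
      g <- genes[gi, ]
      u <- .gene_usage(g, config, srow$condition, srow$compartment)
      n_reads <- rpois(1, depth)
      gp <- true_pas[true_pas$gene_id == g$gene_id, ]
      if (n_reads > 0) {
        cnt <- as.integer(rmultinom(1, n_reads, u))
        for (j in seq_len(nrow(gp))) {
          if (cnt[j] == 0) next
          off <- sample(td$offs, cnt[j], TRUE, prob = td$prob)
          p <- if (g$strand == "+") gp$pos[j] + off else gp$pos[j] - off
          out[[length(out) + 1L]] <- data.table(
            chrom = g$chrom, pos = p, strand = g$strand,
            sample_id = srow$sample_id, origin = gp$pas_id[j])
        }
      }
      if (isTRUE(g$has_decoy)) {
        dg <- decoys[decoys$gene_id == g$gene_id, ]
        nd <- rpois(1, config$artifact_read_fraction * depth)
        if (nd > 0) {
          off <- sample(dd$offs, nd, TRUE, prob = dd$prob)
          p <- if (g$strand == "+") dg$pos[1] + off else dg$pos[1] - off
          out[[length(out) + 1L]] <- data.table(
            chrom = g$chrom, pos = p, strand = g$strand,
            sample_id = srow$sample_id, origin = dg$pas_id[1])
        }
      }
    }
  }
  if (!length(out)) {
    return(data.table(chrom = character(), pos = integer(),
                      strand = character(), sample_id = character(),
                      origin = character()))
  }
  rbindlist(out)
}

#' Simulate CLIP-like peaks around regulated PAS
#'
#' Planted ("bound") genes are the changing genes: each receives one peak
#' whose center sits `peak_offset` +/- `peak_offset_spread` nt from its
#' proximal PAS in transcript orientation. Non-changing genes receive,
#' with probability `background_peak_rate`, one background peak at a
#' random CDS position. Peak metadata records the originating gene and
#' whether the peak was planted at a PAS.
#'
#' @param sim an `apa_sim`.
#' @param tier confidence tier label for the returned [peak_set].
#' @return a `peak_set`; `peaks$planted` marks PAS-anchored peaks.
#' @export
simulate_peaks <- function(sim, tier = "reproducible") {
  stopifnot(inherits(sim, "apa_sim"))
  config <- sim$config
  set.seed(config$rng_seed + 7577L)
  genes <- sim$truth$genes
  pas <- sim$truth$pas
  prox <- pas[pas$type == "true" & pas$rank == 1L, ]
  rows <- list()
  half <- config$peak_width %/% 2L
  for (gi in seq_len(nrow(genes))) {
    g <- genes[gi, ]
    if (isTRUE(g$changing)) {
      pp <- prox[prox$gene_id == g$gene_id, ]
      opts <- seq.int(config$peak_offset - config$peak_offset_spread,
                      config$peak_offset + config$peak_offset_spread)
      off <- opts[sample.int(length(opts), 1)]
      center <- if (g$strand == "+") pp$pos + off else pp$pos - off
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = g$chrom, start = center - half,
        end = center + (config$peak_width - 1L - half),
        strand = g$strand, gene_id = g$gene_id, planted = TRUE,
        summit = center, stringsAsFactors = FALSE)
    } else if (runif(1) < config$background_peak_rate) {
      lo <- if (g$strand == "+") g$start else g$end - g$cds_end_sense + 1L
      hi <- if (g$strand == "+") g$start + g$cds_end_sense - 1L else g$end
      center <- sample(seq.int(lo + 20L, hi - 20L), 1)
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = g$chrom, start = center - half,
        end = center + (config$peak_width - 1L - half),
        strand = g$strand, gene_id = g$gene_id, planted = FALSE,
        summit = center, stringsAsFactors = FALSE)
    }
  }
  df <- do.call(rbind, rows)
  gr <- GRanges(df$chrom, IRanges(df$start, df$end), strand = df$strand)
  gr$name <- df$gene_id
  gr$planted <- df$planted
  gr$peak <- df$summit - df$start
  peak_set(gr, experiment_id = "sim_rbp", cell_context = "sim",
           tier = tier)
}

#' Simulate a DaPars-style dPDUI table
#'
#' Per terminal exon, PDUI (distal usage fraction) per condition is
#' derived from the planted usage vectors with Gaussian noise; dPDUI is
#' control minus knockdown. Adjusted p-values are generated, not
#' computed: small (< 0.01) for planted changing exons and well above
#' the significance threshold (Uniform(0.2, 1)) for planted nulls, so
#' that at zero noise the planted class is recovered exactly by the
#' thresholding layer.
#'
#' @param sim an `apa_sim`.
#' @param noise override of `config$dpdui_noise`.
#' @return list with `table` (data.frame: `exon_id`, `gene_id`,
#'   `PDUI_ctrl`, `PDUI_kd`, `dPDUI`, `p_adj`) and `classes` (named
#'   planted class per exon).
#' @export
simulate_dpdui_table <- function(sim, noise = NULL) {
  stopifnot(inherits(sim, "apa_sim"))
  config <- sim$config
  if (is.null(noise)) noise <- config$dpdui_noise
  set.seed(config$rng_seed + 9151L)
  genes <- sim$truth$genes
  k <- config$pas_per_exon
  n <- nrow(genes)
  pdui_c_true <- rep(config$usage_control[k], n)
  pdui_k_true <- ifelse(genes$changing, config$usage_kd[k],
                        config$usage_control[k])
  clamp01 <- function(x) pmin(1, pmax(0, x))
  pdui_c <- clamp01(pdui_c_true + rnorm(n, 0, noise))
  pdui_k <- clamp01(pdui_k_true + rnorm(n, 0, noise))
  p_adj <- ifelse(genes$changing, runif(n, 1e-6, 0.01), runif(n, 0.2, 1))
  true_delta <- pdui_c_true - pdui_k_true
  classes <- ifelse(!genes$changing, "non_changing",
                    ifelse(true_delta > 0, "rbp_lengthens", "rbp_shortens"))
  names(classes) <- paste0(genes$gene_id, ".te1")
  list(table = data.frame(
    exon_id = paste0(genes$gene_id, ".te1"),
    gene_id = genes$gene_id,
    PDUI_ctrl = pdui_c, PDUI_kd = pdui_k,
    dPDUI = pdui_c - pdui_k, p_adj = p_adj,
    stringsAsFactors = FALSE),
    classes = classes)
}

#' Reference PAS intervals from planted truth
#'
#' Stands in for a curated PAS database (PolyA_DB-like): true PAS
#' positions widened by `slop` nt each side. Decoys are never included.
#'
#' @param sim an `apa_sim`.
#' @param slop half-width in nt.
#' @return GRanges of reference PAS records.
#' @export
reference_pas <- function(sim, slop = 10) {
  p <- sim$truth$pas[sim$truth$pas$type == "true", ]
  gr <- GRanges(p$chrom, IRanges(p$pos - slop, p$pos + slop),
                strand = p$strand)
  gr$name <- p$pas_id
  gr
}

#' Planted PAS positions as anchors
#'
#' @param sim an `apa_sim`.
#' @param rank PAS rank to select (1 = proximal, `pas_per_exon` =
#'   distal); `NULL` for all true PAS.
#' @param genes restrict to these gene ids (`NULL` = all).
#' @return width-1 GRanges of PAS positions with `gene_id`/`pas_id`.
#' @export
pas_anchors <- function(sim, rank = NULL, genes = NULL) {
  p <- sim$truth$pas[sim$truth$pas$type == "true", ]
  if (!is.null(rank)) p <- p[p$rank == rank, ]
  if (!is.null(genes)) p <- p[p$gene_id %in% genes, ]
  gr <- GRanges(p$chrom, IRanges(p$pos, width = 1L), strand = p$strand)
  gr$gene_id <- p$gene_id
  gr$pas_id <- p$pas_id
  gr
}
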