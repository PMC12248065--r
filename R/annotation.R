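# Gene models: spans plus typed features (terminal exon, 3'UTR, CDS, ...).

FEATURE_TYPES <- c("terminal_exon", "utr3", "utr5", "cds",
                   "noncoding_exon", "downstream_flank")

#' Construct a gene_models object
#'
#' A `gene_models` object holds per-gene spans and a typed feature set.
#' Feature types are `terminal_exon`, `utr3`, `utr5`, `cds`,
#' `noncoding_exon` and (after [extend_annotation_downstream]) the
#' `downstream_flank`.
#'
#' @param span [GenomicRanges::GRanges] of gene spans with a `gene_id`
#'   metadata column.
#' @param features GRanges with `gene_id` and `type` metadata columns.
#' @return an object of class `gene_models`.
#' @export
gene_models <- function(span, features) {
  stopifnot(!is.null(span$gene_id), !is.null(features$gene_id),
            !is.null(features$type))
  if (any(as.character(strand(span)) == "*")) {
    stop("unstranded gene span(s): ",
         paste(head(span$gene_id[as.character(strand(span)) == "*"]),
               collapse = ", "))
  }
  bad <- setdiff(unique(features$type), FEATURE_TYPES)
  if (length(bad)) stop("unknown feature type(s): ", paste(bad, collapse = ", "))
  structure(list(span = span, features = features), class = "gene_models")
}

#' @export
print.gene_models <- function(x, ...) {
  cat("gene_models:", length(x$span), "genes,",
      length(x$features), "features\n")
  print(table(x$features$type))
  invisible(x)
}

#' Extract features of one type
#' @param models a `gene_models` object.
#' @param type one of the feature types.
#' @return GRanges of the requested features.
#' @export
gene_features <- function(models, type) {
  stopifnot(inherits(models, "gene_models"), type %in% FEATURE_TYPES)
  models$features[models$features$type == type]
}

#' Read a gene annotation (GTF/GFF or BED12)
#'
#' Builds a [gene_models] object. For each transcript the 3'-most exon in
#' transcript orientation is labelled the terminal exon; when a CDS is
#' present, the exonic region 3' of the CDS end is the 3'UTR (and the
#' region 5' of the CDS start the 5'UTR). Transcripts without a CDS
#' (including BED12 records with `thickStart == thickEnd`) contribute
#' non-coding exons and no 3'UTR.
#'
#' @param path GTF/GFF file (any extension containing "gtf"/"gff") or
#'   BED12 file.
#' @return a `gene_models` object.
#' @export
read_annotation <- function(path) {
  if (grepl("gtf|gff", tolower(path))) {
    gr <- rtracklayer::import(path)
    .models_from_gtf(gr)
  } else {
    gr <- rtracklayer::import(path, format = "BED")
    .models_from_bed12(gr)
  }
}

.check_stranded <- function(gr, what) {
  un <- as.character(strand(gr)) == "*"
  if (any(un)) {
    stop("unstranded ", what, " record(s), e.g. ",
         paste(head(unique(gr$gene_id[un]), 3), collapse = ", "))
  }
}

# per-transcript feature derivation shared by the two readers.
# exons: GRanges of one transcript; cds: GRanges (possibly empty)
.tx_features <- function(exons, cds, gene_id) {
  st <- as.character(strand(exons))[1]
  terminal <- if (st == "+") exons[which.max(end(exons))] else
    exons[which.min(start(exons))]
  feats <- list()
  te <- granges(terminal)
  te$gene_id <- gene_id; te$type <- "terminal_exon"
  feats$te <- te
  if (length(cds) == 0L) {
    nc <- granges(exons)
    nc$gene_id <- gene_id; nc$type <- "noncoding_exon"
    feats$nc <- nc
  } else {
    cg <- granges(GenomicRanges::reduce(cds))
    cg$gene_id <- gene_id; cg$type <- "cds"
    feats$cds <- cg
    chrom <- as.character(seqnames(exons))[1]
    tx_lo <- min(start(exons)); tx_hi <- max(end(exons))
    if (st == "+") {
      bounds <- list(utr3 = c(max(end(cds)) + 1L, tx_hi),
                     utr5 = c(tx_lo, min(start(cds)) - 1L))
    } else {
      bounds <- list(utr3 = c(tx_lo, min(start(cds)) - 1L),
                     utr5 = c(max(end(cds)) + 1L, tx_hi))
    }
    for (nm in names(bounds)) {
      b <- bounds[[nm]]
      if (b[1] > b[2]) next
      reg <- GRanges(chrom, IRanges(b[1], b[2]), strand = st)
      ov <- GenomicRanges::intersect(granges(exons), reg)
      if (length(ov)) {
        ov$gene_id <- gene_id
        ov$type <- nm
        feats[[nm]] <- ov
      }
    }
  }
  feats
}

.models_from_gtf <- function(gr) {
  gr <- gr[gr$type %in% c("gene", "transcript", "mRNA", "exon", "CDS")]
  .check_stranded(gr, "annotation")
  exons <- gr[gr$type == "exon"]
  cds <- gr[gr$type == "CDS"]
  if (length(exons) == 0L) stop("annotation contains no exon records")
  tx_of <- function(x) as.character(x$transcript_id)
  feats <- list(); spans <- list()
  for (tx in unique(tx_of(exons))) {
    e <- exons[tx_of(exons) == tx]
    cc <- cds[tx_of(cds) == tx]
    gid <- as.character(e$gene_id)[1]
    feats[[tx]] <- .tx_features(e, cc, gid)
  }
  features <- do.call(c, unlist(feats, use.names = FALSE))
  # gene spans from gene records when present, else from exon extent
  genes <- gr[gr$type == "gene"]
  if (length(genes)) {
    span <- granges(genes); span$gene_id <- as.character(genes$gene_id)
  } else {
    span_list <- lapply(split(exons, as.character(exons$gene_id)), range)
    gids <- names(span_list)
    span <- unlist(GenomicRanges::GRangesList(lapply(span_list, granges)))
    names(span) <- NULL
    span$gene_id <- gids
  }
  .check_duplicate_genes(span)
  gene_models(span, features)
}

.check_duplicate_genes <- function(span) {
  if (anyDuplicated(span$gene_id)) {
    d <- unique(span$gene_id[duplicated(span$gene_id)])
    key <- paste(span$gene_id, seqnames(span), strand(span))
    if (anyDuplicated(span$gene_id) && length(unique(key)) != length(unique(span$gene_id))) {
      stop("duplicate gene_id(s) with conflicting loci: ",
           paste(head(d, 3), collapse = ", "))
    }
    stop("duplicate gene_id(s): ", paste(head(d, 3), collapse = ", "))
  }
}

.models_from_bed12 <- function(gr) {
  .check_stranded(gr, "BED12")
  feats <- list(); spans <- list()
  blocks <- gr$blocks
  for (i in seq_along(gr)) {
    chrom <- as.character(seqnames(gr))[i]
    st <- as.character(strand(gr))[i]
    gid <- if (!is.null(gr$name)) gr$name[i] else paste0("record_", i)
    bl <- blocks[[i]]
    exons <- GRanges(chrom, IRanges(start(gr)[i] + start(bl) - 1L,
                                    start(gr)[i] + end(bl) - 1L),
                     strand = st)
    thick <- gr$thick[i]
    cds <- if (length(thick) && width(thick) > 1L) {
      GenomicRanges::intersect(
        exons, GRanges(chrom, thick, strand = st))
    } else GRanges()
    feats[[i]] <- .tx_features(exons, cds, gid)
    sp <- granges(gr[i]); sp$gene_id <- gid
    spans[[i]] <- sp
  }
  features <- do.call(c, unlist(feats, use.names = FALSE))
  span <- do.call(c, spans)
  .check_duplicate_genes(span)
  gene_models(span, features)
}

#' Extend gene spans downstream
#'
#' Grows each gene span by `extension` nucleotides past its 3' end in
#' transcript orientation (`end + extension` on "+", `start - extension`
#' on "-", floored at position 1 with a warning). Existing exon/UTR
#' features are unchanged; a `downstream_flank` feature covering the added
#' region is appended per gene. Used to capture binding just past
#' annotated 3' ends (e.g. a 500-nt extension ahead of CLIP peak calling).
#'
#' @param models a `gene_models` object.
#' @param extension non-negative extension length in nt.
#' @return a new `gene_models` object.
#' @export
extend_annotation_downstream <- function(models, extension) {
  stopifnot(inherits(models, "gene_models"), extension >= 0)
  extension <- as.integer(extension)
  span <- models$span
  if (extension == 0L) return(models)
  plus <- as.character(strand(span)) == "+"
  old_end <- end(span); old_start <- start(span)
  new_start <- ifelse(plus, old_start, old_start - extension)
  clamped <- new_start < 1L
  if (any(clamped)) {
    warning("extension clamped at contig start for gene(s): ",
            paste(head(span$gene_id[clamped], 3), collapse = ", "))
    new_start[clamped] <- 1L
  }
  flank <- GRanges(
    seqnames(span),
    IRanges(ifelse(plus, old_end + 1L, new_start),
            ifelse(plus, old_end + extension, pmax(old_start - 1L, 1L))),
    strand = strand(span))
  flank$gene_id <- span$gene_id
  flank$type <- "downstream_flank"
  flank <- flank[width(flank) > 0L]
  end(span)[plus] <- old_end[plus] + extension
  start(span)[!plus] <- new_start[!plus]
  # merge with any existing flank (repeated extension extends the flank)
  old_flank <- models$features$type == "downstream_flank"
  feats <- models$features[!old_flank]
  if (any(old_flank)) {
    prev <- models$features[old_flank]
    merged <- lapply(unique(flank$gene_id), function(g) {
      both <- c(granges(prev[prev$gene_id == g]),
                granges(flank[flank$gene_id == g]))
      r <- GenomicRanges::reduce(both)
      r$gene_id <- g; r$type <- "downstream_flank"
      r
    })
    flank <- do.call(c, merged)
  }
  gene_models(span, c(feats, flank))
}

#' Write gene models as GTF
#'
#' Emits gene, transcript, exon and CDS records (one transcript per gene,
#' exons taken from terminal/noncoding exon features). Sufficient to
#' round-trip annotations produced by the simulator.
#'
#' @param models a `gene_models` object.
#' @param path output GTF path.
#' @export
write_gtf <- function(models, path) {
  stopifnot(inherits(models, "gene_models"))
  lines <- character(0)
  fmt <- function(chrom, feat, s, e, st, gid, tid = NULL) {
    attrs <- paste0("gene_id \"", gid, "\";")
    if (!is.null(tid)) attrs <- paste0(attrs, " transcript_id \"", tid, "\";")
    paste(chrom, "apamap", feat, s, e, ".", st, ".", attrs, sep = "\t")
  }
  for (i in seq_along(models$span)) {
    sp <- models$span[i]
    gid <- sp$gene_id
    tid <- paste0(gid, ".t1")
    chrom <- as.character(seqnames(sp)); st <- as.character(strand(sp))
    lines <- c(lines,
               fmt(chrom, "gene", start(sp), end(sp), st, gid),
               fmt(chrom, "transcript", start(sp), end(sp), st, gid, tid))
    f <- models$features[models$features$gene_id == gid]
    ex <- f[f$type %in% c("terminal_exon", "noncoding_exon")]
    ex <- GenomicRanges::reduce(granges(ex))
    for (j in seq_along(ex)) {
      lines <- c(lines, fmt(chrom, "exon", start(ex)[j], end(ex)[j], st, gid, tid))
    }
    cd <- f[f$type == "cds"]
    for (j in seq_along(cd)) {
      lines <- c(lines, fmt(chrom, "CDS", start(cd)[j], end(cd)[j], st, gid, tid))
    }
  }
  writeLines(lines, path)
  invisible(path)
}
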