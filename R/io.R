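# Readers/writers for the standard formats the pipeline touches.

#' Read a genome FASTA
#'
#' @param path FASTA file.
#' @return named [Biostrings::DNAStringSet]; names truncated at the first
#'   whitespace token.
#' @export
read_genome <- function(path) {
  g <- readDNAStringSet(path)
  names(g) <- sub("\\s.*$", "", names(g))
  g
}

#' Write a genome FASTA
#' @param genome named [Biostrings::DNAStringSet].
#' @param path output file.
#' @export
write_genome <- function(genome, path) {
  writeXStringSet(genome, path)
  invisible(path)
}

#' Read / write BED intervals
#'
#' Thin wrappers over [rtracklayer::import]/[rtracklayer::export] converting
#' between BED (0-based half-open) and the package's internal GRanges
#' (1-based closed) convention. Round-tripping leaves intervals identical.
#'
#' @param path BED file.
#' @return a [GenomicRanges::GRanges].
#' @export
read_bed <- function(path) {
  rtracklayer::import(path, format = "BED")
}

#' @rdname read_bed
#' @param gr a [GenomicRanges::GRanges] to write.
#' @export
write_bed <- function(gr, path) {
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

# narrowPeak extra columns (ENCODE 6+4)
.np_extra <- c(signalValue = "numeric", pValue = "numeric",
               qValue = "numeric", peak = "integer")

#' Read / write ENCODE narrowPeak files
#'
#' @param path narrowPeak (BED6+4) file.
#' @return a [GenomicRanges::GRanges] with `signalValue`, `pValue`,
#'   `qValue` and `peak` (summit offset, -1 if absent) metadata columns.
#' @export
read_narrowpeak <- function(path) {
  rtracklayer::import(path, format = "BED", extraCols = .np_extra)
}

#' @rdname read_narrowpeak
#' @param peaks GRanges; missing narrowPeak columns are filled with
#'   placeholder values (`signalValue` 0, p/q -1, `peak` -1).
#' @export
write_narrowpeak <- function(peaks, path) {
  mc <- mcols(peaks)
  if (is.null(mc$name)) peaks$name <- paste0("peak_", seq_along(peaks))
  if (is.null(mc$score)) peaks$score <- 0L
  for (col in names(.np_extra)) {
    if (is.null(mcols(peaks)[[col]])) {
      mcols(peaks)[[col]] <- if (col == "signalValue") 0 else -1L
    }
  }
  df <- data.frame(
    chrom = as.character(seqnames(peaks)),
    start = start(peaks) - 1L,
    end = end(peaks),
    name = peaks$name,
    score = peaks$score,
    strand = as.character(strand(peaks)),
    signalValue = peaks$signalValue,
    pValue = peaks$pValue,
    qValue = peaks$qValue,
    peak = peaks$peak
  )
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read / write single-nucleotide 3'-end positions
#'
#' 3' read termini are exchanged as BED6 of width-1 intervals. Internally
#' they are a data.table with columns `chrom`, `pos` (1-based), `strand`
#' and `sample_id`.
#'
#' @param paths named character vector of BED files; names are sample ids
#'   (defaults to file basenames).
#' @return a [data.table::data.table] of 3'-end positions.
#' @export
read_ends_bed <- function(paths) {
  if (is.null(names(paths))) {
    names(paths) <- sub("\\.bed$", "", basename(paths))
  }
  rbindlist(lapply(names(paths), function(s) {
    gr <- read_bed(paths[[s]])
    data.table(chrom = as.character(seqnames(gr)), pos = start(gr),
               strand = as.character(strand(gr)), sample_id = s)
  }))
}

#' @rdname read_ends_bed
#' @param ends data.table of 3'-end positions (one sample).
#' @param path output BED file.
#' @export
write_ends_bed <- function(ends, path) {
  gr <- GRanges(ends$chrom, IRanges(ends$pos, width = 1L),
                strand = ends$strand)
  write_bed(gr, path)
}

#' Read a sample manifest
#'
#' A manifest is a TSV with columns `sample_id`, `condition`
#' (control/kd), `compartment` (optional) and `replicate` (integer);
#' knockdown and control samples are paired by (compartment, replicate).
#'
#' @param path TSV file.
#' @return data.frame manifest.
#' @export
read_manifest <- function(path) {
  m <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  req <- c("sample_id", "condition", "replicate")
  if (!all(req %in% names(m))) {
    stop("manifest must have columns: ", paste(req, collapse = ", "))
  }
  if (is.null(m$compartment)) m$compartment <- "whole_cell"
  m
}

#' Write a TSV with provenance comments
#'
#' Standard output format: '#'-prefixed comment lines, then a header line,
#' then tab-separated rows.
#'
#' @param df data.frame to write.
#' @param path output path.
#' @param comments character vector of provenance comment lines (without
#'   the leading '#').
#' @export
write_tsv <- function(df, path, comments = character(0)) {
  con <- file(path, "w")
  on.exit(close(con))
  for (cm in comments) writeLines(paste0("# ", cm), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV written by [write_tsv]
#' @param path file path.
#' @return data.frame.
#' @export
read_tsv <- function(path) {
  read.table(path, header = TRUE, sep = "\t", comment.char = "#",
             stringsAsFactors = FALSE)
}
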