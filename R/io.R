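# Readers/writers for the interchange files. FASTA goes through Biostrings,
# GTF through rtracklayer; the MACS2-style peak tables, CTCF BED and the
# CSV tables are plain headerless/headered text with a documented column
# contract.

#' Read a genome FASTA
#' @param path FASTA file.
#' @return `DNAStringSet` keyed by chromosome.
#' @export
read_genome <- function(path) {
  g <- Biostrings::readDNAStringSet(path)
  names(g) <- sub("\\s.*$", "", names(g))
  g
}

#' Write a genome FASTA
#' @param genome `DNAStringSet`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_genome <- function(genome, path) {
  Biostrings::writeXStringSet(genome, path, width = 70L)
  invisible(path)
}

#' Read gene records from a GTF file
#'
#' Imports via rtracklayer and converts the 1-based inclusive GTF intervals
#' to the package's 0-based half-open convention.
#'
#' @param path GTF file.
#' @return data.frame `gene_id`, `chrom`, `start`, `end`, `strand`.
#' @export
read_gtf_genes <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[gr$type == "gene"]
  data.frame(gene_id = gr$gene_id,
             chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr),
             strand = as.character(GenomicRanges::strand(gr)),
             stringsAsFactors = FALSE)
}

#' Write gene records as GTF
#'
#' @param genes data.frame `gene_id`, `chrom`, `start`, `end`, `strand`
#'   (0-based half-open; converted to GTF's 1-based inclusive on output).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_gtf_genes <- function(genes, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = genes$chrom,
    ranges = IRanges::IRanges(start = genes$start + 1L, end = genes$end),
    strand = genes$strand)
  gr$source <- "chronogrn"
  gr$type <- "gene"
  gr$gene_id <- genes$gene_id
  gr$gene_name <- genes$gene_id
  rtracklayer::export(gr, path, format = "gtf")
  invisible(path)
}

peak_cols <- c("chrom", "start", "end", "name", "score", "strand",
               "signal", "p_score", "q_score", "fold_change")

#' Read a MACS2-style peak table
#'
#' Headerless TSV, broadPeak columns plus a fold-change column:
#' chrom, start, end, name, score, strand, signalValue, pValue(-log10),
#' qValue(-log10), foldChange. Coordinates are 0-based half-open.
#'
#' @param path TSV file.
#' @return data.frame with columns chrom, start, end, name, score, strand,
#'   signal, p_score, q_score, fold_change.
#' @export
read_peak_table <- function(path) {
  empty <- stats::setNames(
    data.frame(character(), integer(), integer(), character(), numeric(),
               character(), numeric(), numeric(), numeric(), numeric(),
               stringsAsFactors = FALSE), peak_cols)
  if (!length(readLines(path, n = 1))) return(empty)
  tab <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE)
  if (ncol(tab) != length(peak_cols))
    stop("peak table must have ", length(peak_cols), " columns, found ",
         ncol(tab))
  names(tab) <- peak_cols
  tab
}

#' Write a MACS2-style peak table
#' @param peaks data.frame as returned by [read_peak_table()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_peak_table <- function(peaks, path) {
  utils::write.table(peaks[, peak_cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a CTCF peak BED (signalValue in column 7)
#' @param path BED file.
#' @return data.frame chrom, start, end, name, score, strand, signal.
#' @export
read_ctcf_bed <- function(path) {
  tab <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE)
  if (ncol(tab) < 7) stop("CTCF BED needs >= 7 columns (signalValue in 7)")
  tab <- tab[, 1:7]
  names(tab) <- c("chrom", "start", "end", "name", "score", "strand",
                  "signal")
  tab
}

#' Write a CTCF peak BED
#' @param ctcf data.frame as returned by [read_ctcf_bed()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_ctcf_bed <- function(ctcf, path) {
  utils::write.table(
    ctcf[, c("chrom", "start", "end", "name", "score", "strand", "signal")],
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read an FPKM table
#'
#' CSV with a `gene` column and one column per sample, named
#' `<condition>_<time>h` (e.g. `uninduced_0h`, `induced_5h`).
#'
#' @param path CSV file.
#' @return data.frame with rownames = gene ids.
#' @export
read_fpkm <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  rownames(tab) <- tab$gene
  tab
}

#' Read a NanoString count table
#'
#' Long CSV: `assay`, `condition`, `time`, `replicate`, `probe`, `class`,
#' `count`, `fields_of_view`, `binding_density`.
#'
#' @param path CSV file.
#' @return data.frame.
#' @export
read_nanostring <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
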