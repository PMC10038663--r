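#' CTCF-bounded regulatory locus of a gene
#'
#' The locus is delimited by the CTCF peak with the highest `signal` wholly
#' or partly within `max_search` bp upstream of the gene start, and likewise
#' downstream of the gene end. The locus runs from the chosen upstream
#' peak's start to the chosen downstream peak's end (outer edges), so a
#' boundary-adjacent site is never dropped. If no peak lies within reach on
#' a side, that flank is capped at gene boundary +/- `max_search` (floored
#' at 0). Signal ties break towards the peak closest to the gene, then the
#' leftmost.
#'
#' @param gene one-row data.frame (or list) with `gene_id`, `chrom`,
#'   `start`, `end` in 0-based half-open coordinates.
#' @param ctcf data.frame of CTCF peaks with `chrom`, `start`, `end`,
#'   `signal`.
#' @param max_search search window per side in bp (default 500000).
#' @return one-row data.frame: `gene_id`, `chrom`, `locus_start`,
#'   `locus_end`, `upstream_capped`, `downstream_capped`.
#' @export
build_locus <- function(gene, ctcf, max_search = 500000) {
  stopifnot(gene$start < gene$end)
  cc <- ctcf[as.character(ctcf$chrom) == as.character(gene$chrom), ,
             drop = FALSE]
  pick <- function(win_lo, win_hi, gene_edge) {
    hit <- cc[cc$start < win_hi & cc$end > win_lo, , drop = FALSE]
    if (!nrow(hit)) return(NULL)
    dist <- pmax(0, pmax(gene_edge - hit$end, hit$start - gene_edge))
    ord <- order(-hit$signal, dist, hit$start)
    hit[ord[1], ]
  }
  up <- pick(max(0, gene$start - max_search), gene$start, gene$start)
  down <- pick(gene$end, gene$end + max_search, gene$end)
  locus_start <- if (is.null(up)) max(0, gene$start - max_search) else up$start
  locus_end <- if (is.null(down)) gene$end + max_search else down$end
  data.frame(gene_id = gene$gene_id, chrom = as.character(gene$chrom),
             locus_start = locus_start, locus_end = locus_end,
             upstream_capped = is.null(up), downstream_capped = is.null(down),
             stringsAsFactors = FALSE)
}

#' Build loci for a gene annotation table
#'
#' @param genes data.frame with `gene_id`, `chrom`, `start`, `end`
#'   (0-based half-open).
#' @inheritParams build_locus
#' @return data.frame of loci, one row per gene.
#' @export
build_loci <- function(genes, ctcf, max_search = 500000) {
  out <- do.call(rbind, lapply(seq_len(nrow(genes)), function(i)
    build_locus(genes[i, ], ctcf, max_search = max_search)))
  rownames(out) <- NULL
  out
}

#' Sites overlapping a regulatory locus
#'
#' Returns the indexed sites overlapping the locus interval by at least one
#' base pair, tagged with the owning gene. A site overlapping two loci
#' appears in both gene's outputs.
#'
#' @param locus one-row locus data.frame from [build_locus()].
#' @param sites indexed-site data.frame (`chrom`, `start`, `end`, ...).
#' @return the overlapping rows of `sites` with a `gene_id` column prepended.
#' @export
sites_in_locus <- function(locus, sites) {
  keep <- as.character(sites$chrom) == as.character(locus$chrom) &
    sites$start < locus$locus_end & sites$end > locus$locus_start
  out <- sites[keep, , drop = FALSE]
  if (nrow(out)) out <- cbind(gene_id = locus$gene_id, out,
                              stringsAsFactors = FALSE)
  else out <- cbind(gene_id = character(), out)
  rownames(out) <- NULL
  out
}

#' Extract site sequences from a genome
#'
#' @param sites data.frame with `chrom`, `start`, `end` (0-based half-open).
#' @param genome a [Biostrings::DNAStringSet] keyed by chromosome name.
#' @return a `DNAStringSet` of uppercase forward-strand sequences named
#'   `chrom:start-end`.
#' @export
extract_sequences <- function(sites, genome) {
  if (!nrow(sites))
    return(Biostrings::DNAStringSet())
  seqs <- lapply(seq_len(nrow(sites)), function(i) {
    chrom <- as.character(sites$chrom[i])
    if (!chrom %in% names(genome))
      stop("chromosome absent from genome: ", chrom)
    len <- length(genome[[chrom]])
    if (sites$start[i] < 0 || sites$end[i] > len)
      stop(sprintf("interval %s:%d-%d beyond contig end (%d bp)",
                   chrom, sites$start[i], sites$end[i], len))
    Biostrings::subseq(genome[[chrom]], start = sites$start[i] + 1L,
                       end = sites$end[i])
  })
  out <- Biostrings::DNAStringSet(seqs)
  out <- Biostrings::DNAStringSet(toupper(out))
  names(out) <- sprintf("%s:%d-%d", sites$chrom, sites$start, sites$end)
  out
}
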