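#' Construct a position weight matrix object
#'
#' @param motif_id identifier (e.g. a JASPAR accession).
#' @param tf transcription-factor name; heterodimer names joined with
#'   `"::"` map to each constituent gene.
#' @param counts 4 x L numeric matrix of column counts or frequencies, rows
#'   named A, C, G, T.
#' @param pseudocount total pseudocount apportioned by background when
#'   converting counts to frequencies (default 0.1, the FIMO default).
#' @param background background base frequencies (default uniform).
#' @return an object of class `pwm`.
#' @export
new_pwm <- function(motif_id, tf, counts, pseudocount = 0.1,
                    background = rep(0.25, 4)) {
  counts <- as.matrix(counts)
  if (nrow(counts) != 4) stop("counts must have 4 rows (A, C, G, T)")
  if (ncol(counts) < 4) stop("motif length must be >= 4")
  if (is.null(rownames(counts))) rownames(counts) <- c("A", "C", "G", "T")
  counts <- counts[c("A", "C", "G", "T"), , drop = FALSE]
  structure(list(motif_id = motif_id, tf = tf,
                 tfs = toupper(strsplit(tf, "::", fixed = TRUE)[[1]]),
                 counts = counts, pseudocount = pseudocount,
                 background = background),
            class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("PWM %s (%s), length %d\n", x$motif_id, x$tf, ncol(x$counts)))
  invisible(x)
}

#' Pseudocounted position frequencies of a PWM
#'
#' f'(b, j) = (count(b, j) + pseudocount * bg(b)) / (total(j) + pseudocount).
#'
#' @param pwm a [new_pwm()] object.
#' @return 4 x L matrix of frequencies (columns sum to 1).
#' @export
pwm_probs <- function(pwm) {
  tot <- colSums(pwm$counts)
  sweep(pwm$counts + pwm$pseudocount * pwm$background, 2,
        tot + pwm$pseudocount, `/`)
}

#' Consensus (per-position argmax) sequence of a PWM
#'
#' @param pwm a [new_pwm()] object.
#' @return character scalar.
#' @export
pwm_consensus <- function(pwm) {
  paste(rownames(pwm$counts)[apply(pwm$counts, 2, which.max)], collapse = "")
}

#' Maximum achievable log-odds score of a PWM
#'
#' @param pwm a [new_pwm()] object.
#' @return numeric scalar.
#' @export
pwm_max_score <- function(pwm) {
  lo <- log2(pwm_probs(pwm) / pwm$background)
  sum(apply(lo, 2, max))
}

#' Log-odds score of a k-mer against a PWM
#'
#' Sum over positions of log2(f'(base)/bg(base)); ambiguity characters (N)
#' contribute 0.
#'
#' @param pwm a [new_pwm()] object.
#' @param kmer character scalar whose length equals the motif length.
#' @return numeric scalar (base-2 log-odds).
#' @export
log_odds_score <- function(pwm, kmer) {
  L <- ncol(pwm$counts)
  bases <- strsplit(toupper(kmer), "")[[1]]
  if (length(bases) != L)
    stop(sprintf("k-mer length %d does not match motif length %d",
                 length(bases), L))
  lo <- log2(pwm_probs(pwm) / pwm$background)
  idx <- match(bases, c("A", "C", "G", "T"))
  sum(ifelse(is.na(idx), 0, lo[cbind(idx, seq_len(L))]))
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# Vectorized scores of every window of `base_idx` (integers 1..4, NA for N)
# against the log-odds matrix `lo`.
window_scores <- function(base_idx, lo) {
  L <- ncol(lo)
  n <- length(base_idx)
  if (n < L) return(numeric(0))
  offsets <- 0:(n - L)
  sc <- numeric(length(offsets))
  for (j in seq_len(L)) {
    idx <- base_idx[offsets + j]
    v <- lo[cbind(idx, j)]
    v[is.na(v)] <- 0
    sc <- sc + v
  }
  sc
}

#' Scan a sequence with a PWM on both strands
#'
#' Every offset is evaluated on the forward strand and on the reverse
#' complement; windows scoring strictly above `threshold` are reported.
#' Minus-strand hits are mapped back to forward-strand offsets, so `offset`
#' always refers to the leftmost base of the matched window on the forward
#' strand; `matched_seq` is the strand-oriented match.
#'
#' @param sequence character scalar (or `DNAString`).
#' @param pwm a [new_pwm()] object.
#' @param threshold minimum score, strict (default 10, the confidence-score
#'   cutoff applied to scan output).
#' @return data.frame `motif_id`, `tf`, `offset` (0-based), `strand`,
#'   `score`, `matched_seq`, ordered by offset then strand.
#' @export
scan_site <- function(sequence, pwm, threshold = 10) {
  sequence <- toupper(as.character(sequence))
  L <- ncol(pwm$counts)
  n <- nchar(sequence)
  empty <- data.frame(motif_id = character(), tf = character(),
                      offset = integer(), strand = character(),
                      score = numeric(), matched_seq = character(),
                      stringsAsFactors = FALSE)
  if (n < L) return(empty)
  lo <- log2(pwm_probs(pwm) / pwm$background)
  fwd_idx <- match(strsplit(sequence, "")[[1]], c("A", "C", "G", "T"))
  rc <- revcomp(sequence)
  rev_idx <- match(strsplit(rc, "")[[1]], c("A", "C", "G", "T"))
  fwd <- window_scores(fwd_idx, lo)
  rev <- window_scores(rev_idx, lo)
  rows <- list()
  hit_f <- which(fwd > threshold)
  for (i in hit_f) {
    off <- i - 1L
    rows[[length(rows) + 1L]] <- data.frame(
      motif_id = pwm$motif_id, tf = pwm$tf, offset = off, strand = "+",
      score = fwd[i], matched_seq = substr(sequence, off + 1L, off + L),
      stringsAsFactors = FALSE)
  }
  hit_r <- which(rev > threshold)
  for (i in hit_r) {
    # offset i-1 on the reverse complement corresponds to forward offset
    # n - L - (i - 1)
    off <- n - L - (i - 1L)
    rows[[length(rows) + 1L]] <- data.frame(
      motif_id = pwm$motif_id, tf = pwm$tf, offset = off, strand = "-",
      score = rev[i], matched_seq = substr(rc, i, i + L - 1L),
      stringsAsFactors = FALSE)
  }
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  out <- out[order(out$offset, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read a motif library (MEME minimal and/or JASPAR pfm files)
#'
#' MEME minimal format: `MOTIF <id> [<tf>]` headers followed by a
#' `letter-probability matrix` block. JASPAR pfm: a `>` header with id and
#' TF name, then four rows of counts (optionally `A [ ... ]` style). TF
#' names are matched case-insensitively against `gene_ids`; heterodimers
#' (`X::Y`) map to every constituent found. Motifs whose TF maps to no gene
#' are kept (with a warning) but contribute no edges downstream.
#'
#' @param files character vector of file paths.
#' @param gene_ids optional character vector of candidate gene ids used to
#'   report unmapped TFs.
#' @param pseudocount passed to [new_pwm()].
#' @return list of `pwm` objects; attribute `n_loaded` carries the count,
#'   which is also reported with `message()`.
#' @export
load_motifs <- function(files, gene_ids = NULL, pseudocount = 0.1) {
  pwms <- list()
  for (f in files) {
    lines <- readLines(f)
    if (any(grepl("^MEME version|^MOTIF", lines))) {
      pwms <- c(pwms, parse_meme_lines(lines, pseudocount))
    } else if (any(grepl("^>", lines))) {
      pwms <- c(pwms, parse_jaspar_lines(lines, pseudocount))
    } else {
      stop("unrecognized motif format in ", f)
    }
  }
  if (!is.null(gene_ids)) {
    gene_ids <- toupper(gene_ids)
    unmapped <- vapply(pwms, function(p) !any(p$tfs %in% gene_ids),
                       logical(1))
    if (any(unmapped))
      warning("motif(s) with no matching gene id: ",
              paste(vapply(pwms[unmapped], `[[`, "", "motif_id"),
                    collapse = ", "))
  }
  message(length(pwms), " motif(s) loaded")
  attr(pwms, "n_loaded") <- length(pwms)
  pwms
}

parse_meme_lines <- function(lines, pseudocount) {
  starts <- grep("^MOTIF", lines)
  ends <- c(starts[-1] - 1L, length(lines))
  out <- list()
  for (k in seq_along(starts)) {
    block <- lines[starts[k]:ends[k]]
    header <- strsplit(trimws(block[1]), "\\s+")[[1]]
    motif_id <- header[2]
    tf <- if (length(header) >= 3) header[3] else header[2]
    mline <- grep("letter-probability matrix", block)
    if (!length(mline)) stop("malformed MEME motif ", motif_id,
                             ": no letter-probability matrix")
    w <- sub(".*w=\\s*(\\d+).*", "\\1", block[mline])
    w <- as.integer(w)
    nsites <- if (grepl("nsites=", block[mline]))
      as.numeric(sub(".*nsites=\\s*([0-9.]+).*", "\\1", block[mline])) else 20
    rows <- block[(mline + 1):(mline + w)]
    mat <- t(vapply(rows, function(r)
      as.numeric(strsplit(trimws(r), "\\s+")[[1]][1:4]), numeric(4)))
    if (any(is.na(mat))) stop("malformed MEME matrix for ", motif_id)
    counts <- t(mat) * nsites
    rownames(counts) <- c("A", "C", "G", "T")
    out[[length(out) + 1L]] <- new_pwm(motif_id, tf, counts,
                                       pseudocount = pseudocount)
  }
  out
}

parse_jaspar_lines <- function(lines, pseudocount) {
  starts <- grep("^>", lines)
  ends <- c(starts[-1] - 1L, length(lines))
  out <- list()
  for (k in seq_along(starts)) {
    block <- lines[starts[k]:ends[k]]
    header <- strsplit(sub("^>\\s*", "", block[1]), "\\s+")[[1]]
    motif_id <- header[1]
    tf <- if (length(header) >= 2) header[2] else header[1]
    body <- block[-1]
    body <- body[nzchar(trimws(body))]
    if (length(body) < 4) stop("malformed JASPAR pfm for ", motif_id)
    parse_row <- function(r) {
      r <- gsub("^[ACGTacgt]\\s*", "", trimws(r))
      r <- gsub("[\\[\\]]", "", r, perl = TRUE)
      as.numeric(strsplit(trimws(r), "\\s+")[[1]])
    }
    mat <- lapply(body[1:4], parse_row)
    L <- unique(vapply(mat, length, integer(1)))
    if (length(L) != 1) stop("ragged JASPAR pfm for ", motif_id)
    counts <- do.call(rbind, mat)
    rownames(counts) <- c("A", "C", "G", "T")
    out[[length(out) + 1L]] <- new_pwm(motif_id, tf, counts,
                                       pseudocount = pseudocount)
  }
  out
}

#' Write a motif library in MEME minimal format
#'
#' @param pwms list of `pwm` objects.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_meme <- function(pwms, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "",
               "strands: + -", "",
               "Background letter frequencies",
               "A 0.25000 C 0.25000 G 0.25000 T 0.25000", ""), con)
  for (p in pwms) {
    tot <- colSums(p$counts)
    freq <- sweep(p$counts, 2, tot, `/`)
    writeLines(sprintf("MOTIF %s %s", p$motif_id, p$tf), con)
    writeLines(sprintf(
      "letter-probability matrix: alength= 4 w= %d nsites= %d E= 0",
      ncol(p$counts), round(max(tot))), con)
    for (j in seq_len(ncol(freq)))
      writeLines(paste(sprintf("%.6f", freq[, j]), collapse = "  "), con)
    writeLines("", con)
  }
  invisible(path)
}

#' Motif hits inside a gene's regulatory sites
#'
#' Scans each site sequence with every library motif whose TF maps
#' (case-insensitively) into the candidate gene set; hits identical in
#' (motif, offset, strand) within a site are deduplicated. Genomic
#' coordinates are derived from the site interval plus the hit offset.
#'
#' @param sites data.frame of sites with `chrom`, `start`, `end` and a
#'   `site_id` column; one row per site.
#' @param seqs `DNAStringSet` of site sequences, parallel to `sites`.
#' @param pwms motif library from [load_motifs()].
#' @param grn_genes character vector of candidate gene ids; motifs mapping
#'   outside this set are skipped.
#' @param threshold score cutoff for [scan_site()].
#' @return data.frame `site_id`, `tf_gene`, `motif_id`, `strand`, `offset`,
#'   `score`, `genomic_start`, `genomic_end`, `matched_seq`.
#' @export
hits_for_gene <- function(sites, seqs, pwms, grn_genes, threshold = 10) {
  grn_up <- toupper(grn_genes)
  rows <- list()
  for (i in seq_len(nrow(sites))) {
    seq_i <- as.character(seqs[[i]])
    for (p in pwms) {
      mapped <- intersect(p$tfs, grn_up)
      if (!length(mapped)) next
      hits <- scan_site(seq_i, p, threshold = threshold)
      if (!nrow(hits)) next
      hits <- hits[!duplicated(hits[, c("motif_id", "offset", "strand")]), ,
                   drop = FALSE]
      for (tf in mapped) {
        gene_match <- grn_genes[match(tf, grn_up)]
        rows[[length(rows) + 1L]] <- data.frame(
          site_id = sites$site_id[i], tf_gene = gene_match,
          motif_id = hits$motif_id, strand = hits$strand,
          offset = hits$offset, score = hits$score,
          genomic_start = sites$start[i] + hits$offset,
          genomic_end = sites$start[i] + hits$offset + ncol(p$counts),
          matched_seq = hits$matched_seq, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows))
    return(data.frame(site_id = character(), tf_gene = character(),
                      motif_id = character(), strand = character(),
                      offset = integer(), score = numeric(),
                      genomic_start = integer(), genomic_end = integer(),
                      matched_seq = character(), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
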