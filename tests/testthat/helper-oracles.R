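# Independent oracles used against the package implementations. These stay
# deliberately naive: the point is a second, slower route to the same
# answer.

# O(n^2) transitive-closure interval merge: repeatedly fuse any two
# intervals on the same chromosome whose separation is <= gap, until stable.
merge_oracle <- function(df, gap = 100) {
  rows <- lapply(seq_len(nrow(df)), function(i)
    list(chrom = as.character(df$chrom[i]), start = df$start[i],
         end = df$end[i], n = 1L))
  repeat {
    fused <- FALSE
    for (i in seq_along(rows)) {
      if (fused) break
      for (j in seq_along(rows)) {
        if (i >= j) next
        a <- rows[[i]]; b <- rows[[j]]
        if (a$chrom != b$chrom) next
        sep <- max(a$start, b$start) - min(a$end, b$end)
        if (sep <= gap) {
          rows[[i]] <- list(chrom = a$chrom, start = min(a$start, b$start),
                            end = max(a$end, b$end), n = a$n + b$n)
          rows[[j]] <- NULL
          fused <- TRUE
          break
        }
      }
    }
    if (!fused) break
  }
  out <- do.call(rbind, lapply(rows, function(r)
    data.frame(chrom = r$chrom, start = r$start, end = r$end, n = r$n,
               stringsAsFactors = FALSE)))
  out[order(out$chrom, out$start), , drop = FALSE]
}

# Exhaustive window scorer: every offset, both strands, explicit
# per-position summation through log_odds_score().
scan_oracle <- function(sequence, pwm, threshold = 10) {
  sequence <- toupper(sequence)
  L <- ncol(pwm$counts)
  n <- nchar(sequence)
  rows <- list()
  if (n >= L) {
    for (off in 0:(n - L)) {
      win <- substr(sequence, off + 1, off + L)
      s <- log_odds_score(pwm, win)
      if (s > threshold)
        rows[[length(rows) + 1L]] <- data.frame(offset = off, strand = "+",
                                                score = s,
                                                stringsAsFactors = FALSE)
      rc <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(win)))
      s2 <- log_odds_score(pwm, rc)
      if (s2 > threshold)
        rows[[length(rows) + 1L]] <- data.frame(offset = off, strand = "-",
                                                score = s2,
                                                stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(offset = integer(), strand = character(),
                      score = numeric(), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  out[order(out$offset, out$strand), , drop = FALSE]
}

random_pwm <- function(L = 8, peaked = FALSE) {
  counts <- matrix(stats::runif(4 * L, 0.5, peaked*96 + 4), 4, L,
                   dimnames = list(c("A", "C", "G", "T"), NULL))
  if (peaked)
    for (j in seq_len(L)) counts[sample(4, 1), j] <- 100
  new_pwm("RND", "RNDTF", counts)
}

random_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")

random_edges <- function(n_nodes, p = 0.25) {
  genes <- sprintf("N%02d", seq_len(n_nodes))
  pairs <- expand.grid(regulator = genes, target = genes,
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$regulator != pairs$target, ]
  keep <- stats::runif(nrow(pairs)) < p
  list(edges = pairs[keep, , drop = FALSE], genes = genes)
}
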