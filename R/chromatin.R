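#' Canonical chromatin-state index table
#'
#' A regulatory site is characterized, at one ChIP time point, by four
#' booleans: presence of H3K27ac and H3K27me3 in induced and in uninduced
#' tissue. Collapsing each tissue to a status in \{none, ac, me3, both\}
#' gives 16 joint states, enumerated as indices 1--16 and grouped into four
#' categories:
#'
#' * `activation` (1--3): the induced tissue gains acetylation and/or loses
#'   methylation relative to uninduced, and neither tissue is bivalent.
#' * `repression` (4--6): the reverse transitions.
#' * `poised` (7--12): at least one tissue carries both marks (bivalent) and
#'   the two tissues differ. Index 7 (me3 to both: the induced tissue gains
#'   acetylation while methylation persists) is the activation-like poised
#'   class used when building the network.
#' * `no_change` (13--16): identical status in both tissues.
#'
#' The enumeration within categories is a package convention; pass a custom
#' table (same columns) to [classify_index()] to transcribe an alternative
#' numbering. Any replacement must keep the printed range semantics
#' (activation 1--3, repression 4--6, poised 7--12, no change 13--16) for
#' [sites_for_network()] to stay meaningful.
#'
#' @return data.frame with columns `index`, `uninduced`, `induced`,
#'   `category`.
#' @export
chromatin_index_table <- function() {
  data.frame(
    index = 1:16,
    uninduced = c("none", "me3", "me3",
                  "ac", "ac", "none",
                  "me3", "none", "ac", "both", "both", "both",
                  "none", "ac", "me3", "both"),
    induced = c("ac", "ac", "none",
                "none", "me3", "me3",
                "both", "both", "both", "ac", "none", "me3",
                "none", "ac", "me3", "both"),
    category = c(rep("activation", 3), rep("repression", 3),
                 rep("poised", 6), rep("no_change", 4)),
    stringsAsFactors = FALSE
  )
}

#' Collapse H3K27ac/H3K27me3 booleans to a tissue status
#'
#' @param ac,me3 logical vectors.
#' @return character vector in `none`, `ac`, `me3`, `both`.
#' @export
mark_status <- function(ac, me3) {
  c("none", "ac", "me3", "both")[1L + as.integer(ac) + 2L * as.integer(me3)]
}

#' Classify the joint H3K27 pattern of a site into the 16-index scheme
#'
#' @param ac_induced,me3_induced,ac_uninduced,me3_uninduced logical vectors
#'   (recycled to common length).
#' @param table index table as returned by [chromatin_index_table()].
#' @return data.frame with columns `index` and `category`.
#' @examples
#' classify_index(TRUE, FALSE, FALSE, TRUE)  # me3 -> ac: activation, index 2
#' @export
classify_index <- function(ac_induced, me3_induced, ac_uninduced,
                           me3_uninduced, table = chromatin_index_table()) {
  n <- max(length(ac_induced), length(me3_induced),
           length(ac_uninduced), length(me3_uninduced))
  ind <- mark_status(rep_len(ac_induced, n), rep_len(me3_induced, n))
  unind <- mark_status(rep_len(ac_uninduced, n), rep_len(me3_uninduced, n))
  key <- paste(unind, ind, sep = ">")
  tab_key <- paste(table$uninduced, table$induced, sep = ">")
  m <- match(key, tab_key)
  if (anyNA(m)) stop("state not covered by index table: ",
                     paste(unique(key[is.na(m)]), collapse = ", "))
  data.frame(index = table$index[m], category = table$category[m],
             stringsAsFactors = FALSE)
}

#' Filter mark-enriched peaks
#'
#' Retains peaks passing all three enrichment cutoffs against input:
#' p-value < 1e-5 (`p_score` > 5 on the -log10 scale), fold change > 1.2,
#' and q-score > 3 (-log10 q). All inequalities are strict.
#'
#' @param peaks data.frame with columns `chrom`, `start`, `end`,
#'   `p_score`, `q_score`, `fold_change` (MACS2 broadPeak-style scores).
#' @param p_score_min,fc_min,q_score_min cutoffs; defaults as above.
#' @return the retained rows of `peaks`.
#' @export
filter_enriched <- function(peaks, p_score_min = 5, fc_min = 1.2,
                            q_score_min = 3) {
  needed <- c("chrom", "start", "end", "p_score", "q_score", "fold_change")
  missing <- setdiff(needed, names(peaks))
  if (length(missing))
    stop("peak table is missing column(s): ", paste(missing, collapse = ", "))
  keep <- peaks$p_score > p_score_min & peaks$fold_change > fc_min &
    peaks$q_score > q_score_min
  peaks[keep, , drop = FALSE]
}

#' Merge intervals with bedtools `merge -d` semantics
#'
#' Intervals (0-based half-open) on the same chromosome whose separation is
#' at most `gap` base pairs are merged transitively after sorting; book-ended
#' and overlapping intervals always merge. Each merged interval records how
#' many inputs it absorbed (`n_sources`) and their collapsed labels
#' (`sources`), mirroring `bedtools merge -d <gap> -c 1,4 -o count,collapse`.
#'
#' @param intervals a data.frame with columns `chrom`, `start`, `end` and
#'   optionally `name`, or a list of such data.frames (list names are used to
#'   label unnamed intervals).
#' @param gap maximum separation (bp) merged across; default 100.
#' @return data.frame `chrom`, `start`, `end`, `n_sources`, `sources`,
#'   sorted by chromosome then start.
#' @export
merge_intervals <- function(intervals, gap = 100) {
  if (is.data.frame(intervals)) intervals <- list(intervals)
  labs <- names(intervals)
  pieces <- lapply(seq_along(intervals), function(i) {
    x <- intervals[[i]]
    if (!nrow(x)) return(NULL)
    if (any(x$start >= x$end)) stop("malformed interval: start >= end")
    nm <- if ("name" %in% names(x)) as.character(x$name)
          else if (!is.null(labs) && nzchar(labs[i])) rep(labs[i], nrow(x))
          else rep(sprintf("set%d", i), nrow(x))
    data.frame(chrom = as.character(x$chrom), start = x$start, end = x$end,
               name = nm, stringsAsFactors = FALSE)
  })
  all <- do.call(rbind, pieces)
  if (is.null(all) || !nrow(all))
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      n_sources = integer(), sources = character(),
                      stringsAsFactors = FALSE))
  all <- all[order(all$chrom, all$start, all$end), , drop = FALSE]
  out <- list()
  cur <- NULL
  flush <- function(cur) {
    data.frame(chrom = cur$chrom, start = cur$start, end = cur$end,
               n_sources = length(cur$names),
               sources = paste(cur$names, collapse = ","),
               stringsAsFactors = FALSE)
  }
  for (i in seq_len(nrow(all))) {
    row <- all[i, ]
    if (is.null(cur) || row$chrom != cur$chrom || row$start - cur$end > gap) {
      if (!is.null(cur)) out[[length(out) + 1L]] <- flush(cur)
      cur <- list(chrom = row$chrom, start = row$start, end = row$end,
                  names = row$name)
    } else {
      cur$end <- max(cur$end, row$end)
      cur$names <- c(cur$names, row$name)
    }
  }
  out[[length(out) + 1L]] <- flush(cur)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Overlap-derived mark state of sites
#'
#' A site carries a mark in a condition iff it overlaps (>= 1 bp) any
#' filtered peak of that mark/condition. Peak sets must already be filtered
#' with [filter_enriched()].
#'
#' @param sites data.frame with `chrom`, `start`, `end`.
#' @param peak_sets named list with elements `ac_induced`, `me3_induced`,
#'   `ac_uninduced`, `me3_uninduced`, each a peak data.frame (possibly empty).
#' @return logical matrix, one row per site, columns as above. Sites on a
#'   chromosome absent from every peak set get all-FALSE with a warning.
#' @export
mark_state_at <- function(sites, peak_sets) {
  needed <- c("ac_induced", "me3_induced", "ac_uninduced", "me3_uninduced")
  if (!all(needed %in% names(peak_sets)))
    stop("peak_sets must contain: ", paste(needed, collapse = ", "))
  peak_chroms <- unique(unlist(lapply(peak_sets, function(p)
    if (nrow(p)) as.character(p$chrom) else character())))
  unknown <- setdiff(unique(as.character(sites$chrom)), peak_chroms)
  if (length(unknown) && length(peak_chroms))
    warning("site chromosome(s) absent from all peak sets: ",
            paste(unknown, collapse = ", "))
  out <- sapply(needed, function(k) {
    p <- peak_sets[[k]]
    if (!nrow(p)) return(rep(FALSE, nrow(sites)))
    vapply(seq_len(nrow(sites)), function(i) {
      any(p$chrom == sites$chrom[i] & p$start < sites$end[i] &
            p$end > sites$start[i])
    }, logical(1))
  })
  out <- matrix(as.logical(out), nrow = nrow(sites),
                dimnames = list(NULL, needed))
  out
}

#' Derive indexed sites at one ChIP time point
#'
#' Filters the four peak sets, merges their union into unique sites
#' (bedtools semantics, `gap` bp), and classifies each site's joint H3K27
#' pattern into the 16-index scheme.
#'
#' @param peak_sets named list of raw peak data.frames (`ac_induced`,
#'   `me3_induced`, `ac_uninduced`, `me3_uninduced`).
#' @param chip_time ChIP time point in hours, recorded on the output.
#' @param gap merge gap in bp (default 100).
#' @param table index table, see [chromatin_index_table()].
#' @param filter apply [filter_enriched()] first (default TRUE).
#' @return data.frame of indexed sites: `chrom`, `start`, `end`,
#'   `chip_time`, `index`, `category`, `n_sources`, `sources`.
#' @export
derive_indexed_sites <- function(peak_sets, chip_time, gap = 100,
                                 table = chromatin_index_table(),
                                 filter = TRUE) {
  needed <- c("ac_induced", "me3_induced", "ac_uninduced", "me3_uninduced")
  sets <- peak_sets[needed]
  if (filter) sets <- lapply(sets, filter_enriched)
  sites <- merge_intervals(sets, gap = gap)
  if (!nrow(sites)) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), chip_time = numeric(),
                      index = integer(), category = character(),
                      n_sources = integer(), sources = character(),
                      stringsAsFactors = FALSE))
  }
  st <- mark_state_at(sites, sets)
  cls <- classify_index(st[, "ac_induced"], st[, "me3_induced"],
                        st[, "ac_uninduced"], st[, "me3_uninduced"],
                        table = table)
  data.frame(chrom = sites$chrom, start = sites$start, end = sites$end,
             chip_time = chip_time, index = cls$index,
             category = cls$category, n_sources = sites$n_sources,
             sources = sites$sources, stringsAsFactors = FALSE)
}

#' Select indexed sites for network construction
#'
#' @param sites data.frame with an `index` column ([derive_indexed_sites()]).
#' @param mode `"activation_only"` (indices 1--3 and 7, the main-network
#'   rule), `"activation_and_repression"` (1--7, subnetworks), or
#'   `"all_changing"` (1--10).
#' @return the selected rows.
#' @export
sites_for_network <- function(sites,
                              mode = c("activation_only",
                                       "activation_and_repression",
                                       "all_changing")) {
  mode <- match.arg(mode)
  keep <- switch(mode,
                 activation_only = c(1:3, 7),
                 activation_and_repression = 1:7,
                 all_changing = 1:10)
  sites[sites$index %in% keep, , drop = FALSE]
}
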