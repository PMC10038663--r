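#' Per-gene outdegree at one time point
#'
#' The outdegree of a component is its number of outgoing interactions,
#' including any self-loop. By default sign-distinct parallel interactions
#' to the same target count separately (interactions, not arcs); set
#' `distinct_targets = TRUE` to count each (regulator, target) pair once.
#'
#' @param edges edge data.frame (`regulator`, `target`, `sign`) for one
#'   time point.
#' @param genes gene ids to report (must cover all edge endpoints).
#' @param distinct_targets collapse sign-distinct duplicates (default
#'   FALSE).
#' @return named integer vector over `genes`.
#' @export
outdegree <- function(edges, genes, distinct_targets = FALSE) {
  unknown <- setdiff(unique(c(edges$regulator, edges$target)), genes)
  if (length(unknown)) stop("unknown gene(s): ",
                            paste(unknown, collapse = ", "))
  if (distinct_targets)
    edges <- edges[!duplicated(edges[, c("regulator", "target")]), ,
                   drop = FALSE]
  out <- table(factor(edges$regulator, levels = genes))
  stats::setNames(as.integer(out), genes)
}

#' Directed betweenness centrality
#'
#' CB_i = sum over ordered pairs (s, u), s != u, s != i != u, with at least
#' one directed path from s to u, of sigma_su(i)/sigma_su, where sigma
#' counts distinct shortest directed paths. Unnormalized; unreachable pairs
#' contribute 0; self-loops and the sign of parallel interactions are
#' ignored for path topology (edges collapse to single arcs).
#'
#' @param edges edge data.frame (`regulator`, `target`) for one time point.
#' @param genes gene ids defining the node set.
#' @return named numeric vector over `genes`.
#' @export
betweenness <- function(edges, genes) {
  unknown <- setdiff(unique(c(edges$regulator, edges$target)), genes)
  if (length(unknown)) stop("unknown gene(s): ",
                            paste(unknown, collapse = ", "))
  n <- length(genes)
  adj <- matrix(0L, n, n)
  if (nrow(edges)) {
    i <- match(edges$regulator, genes)
    j <- match(edges$target, genes)
    keep <- i != j
    adj[cbind(i[keep], j[keep])] <- 1L
  }
  stats::setNames(cpp_betweenness(adj), genes)
}

#' Brute-force betweenness oracle
#'
#' Independent route for validation: enumerates every simple directed path
#' between each ordered pair by depth-first search and credits interior
#' vertices of the shortest ones. Exponential; small graphs only.
#'
#' @inheritParams betweenness
#' @return named numeric vector over `genes`.
#' @export
betweenness_bruteforce <- function(edges, genes) {
  n <- length(genes)
  adj <- matrix(0L, n, n)
  if (nrow(edges)) {
    i <- match(edges$regulator, genes)
    j <- match(edges$target, genes)
    keep <- i != j
    adj[cbind(i[keep], j[keep])] <- 1L
  }
  stats::setNames(cpp_betweenness_brute(adj), genes)
}

#' Exhaustive agreement check of the two betweenness routes
#'
#' Runs both the BFS implementation and the path-enumeration oracle on
#' every labelled digraph (no self-loops) with `n` nodes and returns the
#' number of graphs checked and the maximum absolute discrepancy.
#'
#' @param n node count, 1--5.
#' @return list with `n_graphs` and `max_abs_diff`.
#' @export
check_betweenness_exhaustive <- function(n) {
  cpp_check_betweenness_exhaustive(as.integer(n))
}

#' Centrality records and core-gene ranking at one time point
#'
#' Genes are ranked by betweenness with outdegree as tiebreak (then gene id
#' for determinism). A gene is flagged `core` when it sits at or above the
#' `quantile` cutoff in *both* metrics; in a single-gene graph the gene is
#' core by vacuity.
#'
#' @param edges edge data.frame for one time point.
#' @param genes node set.
#' @param time time point recorded on the output.
#' @param quantile core cutoff (default 0.9: top 10%).
#' @param distinct_targets passed to [outdegree()].
#' @return data.frame `gene`, `time`, `outdegree`, `betweenness`, `core`,
#'   ordered by rank.
#' @export
rank_core <- function(edges, genes, time = NA_real_, quantile = 0.9,
                      distinct_targets = FALSE) {
  if (!length(genes))
    return(data.frame(gene = character(), time = numeric(),
                      outdegree = integer(), betweenness = numeric(),
                      core = logical(), stringsAsFactors = FALSE))
  od <- outdegree(edges, genes, distinct_targets = distinct_targets)
  cb <- betweenness(edges, genes)
  ord <- order(-cb, -od, genes)
  if (length(genes) == 1) {
    core <- TRUE
  } else {
    cb_cut <- stats::quantile(cb, quantile, names = FALSE, type = 7)
    od_cut <- stats::quantile(od, quantile, names = FALSE, type = 7)
    core <- cb >= cb_cut & od >= od_cut
  }
  out <- data.frame(gene = genes, time = time, outdegree = as.integer(od),
                    betweenness = as.numeric(cb), core = core,
                    stringsAsFactors = FALSE)[ord, ]
  rownames(out) <- NULL
  out
}

#' Network metrics across all time points of a GRN
#'
#' @param grn a `timed_grn` (ideally pruned).
#' @param quantile,distinct_targets passed to [rank_core()].
#' @return data.frame of per-gene, per-time centrality records.
#' @export
grn_metrics <- function(grn, quantile = 0.9, distinct_targets = FALSE) {
  out <- lapply(grn$time_points, function(t) {
    e <- grn$edges[grn$edges$time == t, , drop = FALSE]
    rank_core(e, grn$genes, time = t, quantile = quantile,
              distinct_targets = distinct_targets)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
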