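#' Map a network time point to its ChIP epoch
#'
#' Chromatin was profiled at a coarser grid than expression; each network
#' time point borrows the nearest available epoch at or after it: 0--5 h use
#' the 5 h chromatin data, 7--9 h the 9 h data, and 12 h the 12 h data. The
#' 0 h assignment (no dedicated epoch exists) falls back to the earliest
#' one.
#'
#' @param t time point in hours; must belong to `time_points`.
#' @param chip_times sorted ChIP epochs (default 5, 9, 12).
#' @param time_points declared network time points.
#' @return the ChIP epoch in hours.
#' @examples
#' chip_epoch(3)   # 5
#' chip_epoch(7)   # 9
#' @export
chip_epoch <- function(t, chip_times = c(5, 9, 12),
                       time_points = c(0, 1, 3, 5, 7, 9, 12)) {
  if (!t %in% time_points) stop("unknown time point: ", t)
  chip_times <- sort(chip_times)
  ge <- chip_times[chip_times >= t]
  if (length(ge)) ge[1] else max(chip_times)
}

#' Sign of a predicted interaction under the regulatory rule table
#'
#' At sites undergoing activation, a regulator and target changing in the
#' same direction yield a positive interaction and opposing directions a
#' negative one. At repressed sites the rules are reversed, and no
#' interaction is predicted when the regulator is not expressed (direction
#' `none`); targets with direction `none` receive no interactions in either
#' mode.
#'
#' @param reg_dir,tgt_dir directions in `up`, `down`, `none`.
#' @param site_class `"activation"` or `"repression"`.
#' @return `"positive"`, `"negative"`, or `NA_character_` for no edge.
#' @export
edge_sign <- function(reg_dir, tgt_dir, site_class = "activation") {
  if (reg_dir == "none" || tgt_dir == "none") return(NA_character_)
  same <- reg_dir == tgt_dir
  if (site_class == "activation") {
    if (same) "positive" else "negative"
  } else {
    if (same) "negative" else "positive"
  }
}

# Regulator direction under the temporal gate: the call at t, falling back
# to the immediately preceding declared time point ("simultaneously or just
# before").
regulator_direction <- function(profile, gene, t, time_points) {
  d <- profile_direction(profile, gene, t)
  if (d != "none") return(d)
  earlier <- time_points[time_points < t]
  if (!length(earlier)) return("none")
  profile_direction(profile, gene, max(earlier))
}

#' Infer signed edges at one time point
#'
#' For every target whose direction at `t` is nonzero, every candidate site
#' of its locus carrying a TF hit contributes an edge when the TF passes the
#' temporal gate (nonzero direction at `t` or at the immediately preceding
#' time point); the sign follows [edge_sign()] with the site's class.
#'
#' @param t time point (hours).
#' @param profile integrated profile ([integrate_platforms()]).
#' @param site_hits data.frame with columns `target_gene`, `site_id`,
#'   `site_class` (`activation`/`repression`), `tf_gene`, already restricted
#'   to sites of the ChIP epoch serving `t`.
#' @param time_points declared time points (for the temporal gate).
#' @return data.frame `regulator`, `target`, `sign`, `time`, `site_id`,
#'   `site_class` (possibly zero rows).
#' @export
infer_edges_at <- function(t, profile, site_hits,
                           time_points = c(0, 1, 3, 5, 7, 9, 12)) {
  empty <- data.frame(regulator = character(), target = character(),
                      sign = character(), time = numeric(),
                      site_id = character(), site_class = character(),
                      stringsAsFactors = FALSE)
  if (!nrow(site_hits)) return(empty)
  tgt_dirs <- vapply(unique(site_hits$target_gene), function(g)
    profile_direction(profile, g, t), character(1))
  reg_dirs <- vapply(unique(site_hits$tf_gene), function(g)
    regulator_direction(profile, g, t, time_points), character(1))
  rows <- list()
  for (i in seq_len(nrow(site_hits))) {
    td <- tgt_dirs[[site_hits$target_gene[i]]]
    if (td == "none") next
    rd <- reg_dirs[[site_hits$tf_gene[i]]]
    s <- edge_sign(rd, td, site_hits$site_class[i])
    if (is.na(s)) next
    rows[[length(rows) + 1L]] <- data.frame(
      regulator = site_hits$tf_gene[i], target = site_hits$target_gene[i],
      sign = s, time = t, site_id = site_hits$site_id[i],
      site_class = site_hits$site_class[i], stringsAsFactors = FALSE)
  }
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Remove duplicated interactions
#'
#' Interactions are unique on (regulator, target, sign, time); duplicates
#' arising from a regulator binding several sites of the same target are
#' collapsed, with the supporting site ids unioned (comma-separated,
#' sorted).
#'
#' @param edges edge data.frame from [infer_edges_at()].
#' @return deduplicated edge data.frame with a `sites` column.
#' @export
dedup_edges <- function(edges) {
  if (!nrow(edges))
    return(data.frame(regulator = character(), target = character(),
                      sign = character(), time = numeric(),
                      sites = character(), stringsAsFactors = FALSE))
  key <- paste(edges$regulator, edges$target, edges$sign, edges$time,
               sep = "\r")
  site_col <- if ("sites" %in% names(edges)) edges$sites else edges$site_id
  agg <- tapply(site_col, key, function(s)
    paste(sort(unique(unlist(strsplit(s, ",")))), collapse = ","))
  first <- !duplicated(key)
  out <- data.frame(regulator = edges$regulator[first],
                    target = edges$target[first],
                    sign = edges$sign[first], time = edges$time[first],
                    sites = as.character(agg[key[first]]),
                    stringsAsFactors = FALSE)
  out <- out[order(out$time, out$regulator, out$target, out$sign), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Assemble a time-resolved GRN
#'
#' @param profile integrated expression profile.
#' @param site_hits data.frame with columns `target_gene`, `site_id`,
#'   `chip_time`, `site_class`, `tf_gene` covering all ChIP epochs.
#' @param genes candidate gene ids (network node set before pruning).
#' @param time_points network time points.
#' @param chip_times ChIP epochs.
#' @return object of class `timed_grn`: list with `edges` (deduplicated),
#'   `genes`, `profile`, `time_points`, `pruned` (ids removed as isolated,
#'   filled by [prune_isolated()]).
#' @export
build_grn <- function(profile, site_hits, genes,
                      time_points = c(0, 1, 3, 5, 7, 9, 12),
                      chip_times = c(5, 9, 12)) {
  all_edges <- list()
  for (t in time_points) {
    e <- chip_epoch(t, chip_times, time_points)
    sh <- site_hits[site_hits$chip_time == e, , drop = FALSE]
    all_edges[[length(all_edges) + 1L]] <-
      infer_edges_at(t, profile, sh, time_points)
  }
  edges <- dedup_edges(do.call(rbind, all_edges))
  structure(list(edges = edges, genes = genes, profile = profile,
                 time_points = time_points, pruned = character()),
            class = "timed_grn")
}

#' @export
print.timed_grn <- function(x, ...) {
  cat(sprintf("timed_grn: %d gene(s), %d interaction(s) over %d time point(s)\n",
              length(x$genes), nrow(x$edges), length(x$time_points)))
  invisible(x)
}

#' Prune genes without any interaction
#'
#' Removes genes with neither incoming nor outgoing interactions at any time
#' point (a self-loop counts as an interaction). Idempotent.
#'
#' @param grn a `timed_grn`.
#' @return the pruned `timed_grn`; removed ids are in `$pruned`.
#' @export
prune_isolated <- function(grn) {
  connected <- unique(c(grn$edges$regulator, grn$edges$target))
  removed <- setdiff(grn$genes, connected)
  grn$pruned <- union(grn$pruned, removed)
  grn$genes <- intersect(grn$genes, connected)
  grn
}

#' Site-resolved subnetwork of one target gene
#'
#' Candidate sites of the target's locus with indices 1--7 (activation or
#' repression) at any ChIP epoch are merged across epochs (bedtools
#' semantics, `merge_gap` bp); each merged site becomes a named network node
#' (`<gene>_site1`, ... ordered by coordinate). At each time point, a node
#' whose state at the serving epoch is activation or repression receives
#' TF-to-site edges under the rule table, using the owner gene's direction
#' as the target direction; per-epoch node activity is recorded.
#'
#' @param target_gene gene id.
#' @param sites indexed sites of the target's locus across epochs
#'   (columns `chrom`, `start`, `end`, `chip_time`, `index`, `category`,
#'   `site_id`).
#' @param hits data.frame `site_id`, `tf_gene` of motif hits in those sites.
#' @param profile integrated expression profile.
#' @param time_points,chip_times as in [build_grn()].
#' @param merge_gap cross-epoch merge distance in bp (default 500).
#' @return list with `nodes` (`node`, `chrom`, `start`, `end`), `activity`
#'   (`node`, `chip_time`, `index`, `category`), and `edges` (`tf_gene`,
#'   `node`, `sign`, `time`).
#' @export
build_subnetwork <- function(target_gene, sites, hits, profile,
                             time_points = c(0, 1, 3, 5, 7, 9, 12),
                             chip_times = c(5, 9, 12), merge_gap = 500) {
  sites <- sites[sites$index %in% 1:7, , drop = FALSE]
  empty_nodes <- data.frame(node = character(), chrom = character(),
                            start = integer(), end = integer(),
                            stringsAsFactors = FALSE)
  if (!nrow(sites))
    return(list(nodes = empty_nodes,
                activity = data.frame(node = character(),
                                      chip_time = numeric(),
                                      index = integer(),
                                      category = character(),
                                      stringsAsFactors = FALSE),
                edges = data.frame(tf_gene = character(), node = character(),
                                   sign = character(), time = numeric(),
                                   stringsAsFactors = FALSE)))
  merged <- merge_intervals(
    data.frame(chrom = sites$chrom, start = sites$start, end = sites$end,
               name = sites$site_id, stringsAsFactors = FALSE),
    gap = merge_gap)
  merged$node <- sprintf("%s_site%d", target_gene, seq_len(nrow(merged)))
  # map each epoch-specific component site to its merged node
  comp_node <- vapply(seq_len(nrow(sites)), function(i) {
    j <- which(merged$chrom == sites$chrom[i] &
                 merged$start <= sites$start[i] & merged$end >= sites$end[i])
    merged$node[j[1]]
  }, character(1))
  activity <- data.frame(node = comp_node, chip_time = sites$chip_time,
                         index = sites$index, category = sites$category,
                         stringsAsFactors = FALSE)
  activity <- activity[order(activity$node, activity$chip_time), ,
                       drop = FALSE]
  rownames(activity) <- NULL

  edges <- list()
  for (t in time_points) {
    e <- chip_epoch(t, chip_times, time_points)
    tgt_dir <- profile_direction(profile, target_gene, t)
    if (tgt_dir == "none") next
    comp_at <- which(sites$chip_time == e)
    for (i in comp_at) {
      cls <- if (sites$index[i] %in% c(1:3, 7)) "activation"
             else "repression"
      h <- hits[hits$site_id == sites$site_id[i], , drop = FALSE]
      for (tf in unique(h$tf_gene)) {
        rd <- regulator_direction(profile, tf, t, time_points)
        s <- edge_sign(rd, tgt_dir, cls)
        if (is.na(s)) next
        edges[[length(edges) + 1L]] <- data.frame(
          tf_gene = tf, node = comp_node[i], sign = s, time = t,
          stringsAsFactors = FALSE)
      }
    }
  }
  edges <- if (length(edges)) do.call(rbind, edges)
           else data.frame(tf_gene = character(), node = character(),
                           sign = character(), time = numeric(),
                           stringsAsFactors = FALSE)
  edges <- edges[!duplicated(edges), , drop = FALSE]
  edges <- edges[order(edges$time, edges$node, edges$tf_gene), , drop = FALSE]
  rownames(edges) <- NULL
  list(nodes = merged[, c("node", "chrom", "start", "end")],
       activity = activity, edges = edges)
}

#' Export a network in the BioTapestry interchange dialect
#'
#' Writes a Model Hierarchy CSV (model/region/node/link rows; positive
#' interactions encoded as `enhance`, negative as `repress`) and a Time
#' Expression XML file (per-gene, per-hour expression states). The dialect
#' is the documented minimal subset round-tripped by
#' [parse_biotapestry_csv()] and [parse_biotapestry_xml()].
#'
#' @param grn a `timed_grn`.
#' @param csv_path,xml_path output file paths.
#' @param model model name written to the CSV (default "grn").
#' @return invisible list of the two paths.
#' @export
export_biotapestry <- function(grn, csv_path, xml_path, model = "grn") {
  edges <- grn$edges
  lines <- c("command,model,arg1,arg2,arg3,arg4",
             sprintf("model,%s,,,,", model))
  for (t in grn$time_points)
    lines <- c(lines, sprintf("region,%s,%sh,,,", model, t))
  for (g in sort(grn$genes))
    lines <- c(lines, sprintf("node,%s,%s,,,", model, g))
  if (nrow(edges)) {
    sgn <- ifelse(edges$sign == "positive", "enhance", "repress")
    lines <- c(lines, sprintf("link,%s,%s,%s,%s,%s", model,
                              edges$regulator, edges$target, sgn,
                              edges$time))
  }
  writeLines(lines, csv_path)

  root <- xml2::xml_new_root("timeExpression")
  prof <- grn$profile[grn$profile$gene %in% grn$genes, , drop = FALSE]
  for (g in sort(unique(prof$gene))) {
    gnode <- xml2::xml_add_child(root, "gene", name = g)
    sub <- prof[prof$gene == g, , drop = FALSE]
    sub <- sub[order(sub$time), , drop = FALSE]
    for (i in seq_len(nrow(sub)))
      xml2::xml_add_child(gnode, "expression",
                          time = format(sub$time[i]),
                          state = sub$direction[i])
  }
  xml2::write_xml(root, xml_path)
  invisible(list(csv = csv_path, xml = xml_path))
}

#' Parse a Model Hierarchy CSV written by [export_biotapestry()]
#'
#' @param path CSV path.
#' @return list with `model`, `regions`, `nodes`, and `edges` (`regulator`,
#'   `target`, `sign`, `time`).
#' @export
parse_biotapestry_csv <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  links <- tab[tab$command == "link", , drop = FALSE]
  edges <- data.frame(
    regulator = as.character(links$arg1),
    target = as.character(links$arg2),
    sign = ifelse(links$arg3 == "enhance", "positive", "negative"),
    time = as.numeric(links$arg4), stringsAsFactors = FALSE)
  if (!nrow(edges)) edges$sign <- character()
  list(model = tab$model[tab$command == "model"][1],
       regions = tab$arg1[tab$command == "region"],
       nodes = tab$arg1[tab$command == "node"],
       edges = edges)
}

#' Parse a Time Expression XML written by [export_biotapestry()]
#'
#' @param path XML path.
#' @return data.frame `gene`, `time`, `direction`.
#' @export
parse_biotapestry_xml <- function(path) {
  doc <- xml2::read_xml(path)
  genes <- xml2::xml_find_all(doc, ".//gene")
  rows <- lapply(genes, function(g) {
    ex <- xml2::xml_find_all(g, ".//expression")
    data.frame(gene = xml2::xml_attr(g, "name"),
               time = as.numeric(xml2::xml_attr(ex, "time")),
               direction = xml2::xml_attr(ex, "state"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- data.frame(gene = character(), time = numeric(),
                                      direction = character(),
                                      stringsAsFactors = FALSE)
  out
}

#' Write intervals as a browser BED track
#'
#' 0-based half-open coordinates, deterministic ordering (chrom, start,
#' end, name), one `track` header line. Empty input yields a header-only
#' file.
#'
#' @param intervals data.frame with `chrom`, `start`, `end` and optionally
#'   `name`, `score`, `strand`.
#' @param path output file.
#' @param track_name track name for the header.
#' @return `path`, invisibly.
#' @export
export_bed <- function(intervals, path, track_name = "track") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf('track name="%s"', track_name), con)
  if (nrow(intervals)) {
    name <- if ("name" %in% names(intervals)) as.character(intervals$name)
            else rep(".", nrow(intervals))
    score <- if ("score" %in% names(intervals)) intervals$score
             else rep(0, nrow(intervals))
    strand <- if ("strand" %in% names(intervals))
                as.character(intervals$strand)
              else rep(".", nrow(intervals))
    ord <- order(intervals$chrom, intervals$start, intervals$end, name)
    writeLines(sprintf("%s\t%d\t%d\t%s\t%s\t%s",
                       intervals$chrom[ord], as.integer(intervals$start[ord]),
                       as.integer(intervals$end[ord]), name[ord],
                       format(score[ord], trim = TRUE), strand[ord]), con)
  }
  invisible(path)
}

#' Read a BED track written by [export_bed()]
#'
#' @param path BED path.
#' @return data.frame `chrom`, `start`, `end`, `name`, `score`, `strand`.
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^track", lines) & nzchar(lines)]
  if (!length(lines))
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), name = character(), score = numeric(),
                      strand = character(), stringsAsFactors = FALSE))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  data.frame(chrom = vapply(parts, `[`, "", 1),
             start = as.integer(vapply(parts, `[`, "", 2)),
             end = as.integer(vapply(parts, `[`, "", 3)),
             name = vapply(parts, `[`, "", 4),
             score = as.numeric(vapply(parts, `[`, "", 5)),
             strand = vapply(parts, `[`, "", 6), stringsAsFactors = FALSE)
}
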