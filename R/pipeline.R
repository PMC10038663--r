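# End-to-end orchestration: scenario directory -> expression calls ->
# indexed sites -> loci -> motif hits -> timed GRN -> metrics -> exports.

#' RNA-seq direction calls from an FPKM table
#'
#' Applies [classify_time_zero()] at 0 h and [classify_fpkm()] at the
#' remaining RNA-seq time points.
#'
#' @param fpkm data.frame from [read_fpkm()].
#' @param times RNA-seq time points (default 0, 5, 9, 12).
#' @param min_fpkm,up_fc,down_fc thresholds for [classify_fpkm()].
#' @return data.frame `gene`, `time`, `direction`.
#' @export
rnaseq_calls <- function(fpkm, times = c(0, 5, 9, 12), min_fpkm = 10,
                         up_fc = 1.5, down_fc = 0.5) {
  rows <- list()
  for (t in times) {
    if (t == 0) {
      d <- classify_time_zero(fpkm[["uninduced_0h"]], fpkm[["induced_5h"]],
                              fpkm[["uninduced_5h"]])
    } else {
      d <- classify_fpkm(fpkm[[sprintf("induced_%gh", t)]],
                         fpkm[[sprintf("uninduced_%gh", t)]],
                         up_fc = up_fc, down_fc = down_fc,
                         min_fpkm = min_fpkm)
    }
    rows[[length(rows) + 1L]] <- data.frame(gene = fpkm$gene, time = t,
                                            direction = d,
                                            stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' NanoString direction calls from raw assays
#'
#' Normalizes with [nanostring_normalize()] and calls each gene at each
#' time point with [nanostring_de()] on the triplicate normalized counts.
#'
#' @param nanostring long count table ([read_nanostring()]): columns
#'   `assay`, `condition`, `time`, `replicate`, `probe`, `class`, `count`
#'   (+ QC columns).
#' @param up,down,alpha thresholds for [nanostring_de()].
#' @return data.frame `gene`, `time`, `direction`, plus attributes
#'   `normalized` (the endogenous matrix) and `stats` (per-call FC and p).
#' @export
nanostring_calls <- function(nanostring, up = 1.2, down = 0.8,
                             alpha = 0.05) {
  norm <- nanostring_normalize(nanostring)
  endo <- norm$endogenous
  meta <- unique(nanostring[, c("assay", "condition", "time", "replicate")])
  meta <- meta[meta$assay %in% colnames(endo), ]
  rows <- list()
  stats_rows <- list()
  for (t in sort(unique(meta$time))) {
    ind_assays <- meta$assay[meta$condition == "induced" & meta$time == t]
    un_assays <- meta$assay[meta$condition == "uninduced" & meta$time == t]
    for (g in rownames(endo)) {
      de <- nanostring_de(endo[g, ind_assays], endo[g, un_assays],
                          up = up, down = down, alpha = alpha)
      rows[[length(rows) + 1L]] <- data.frame(gene = g, time = t,
                                              direction = de$direction,
                                              stringsAsFactors = FALSE)
      stats_rows[[length(stats_rows) + 1L]] <- data.frame(
        gene = g, time = t, fc = de$fc, p = de$p, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "normalized") <- endo
  attr(out, "stats") <- do.call(rbind, stats_rows)
  out
}

#' Run the full GRN-construction pipeline on a scenario directory
#'
#' Reads the input bundle (as written by [generate_scenario()] or
#' assembled with the same file contract), derives the integrated
#' expression profile, indexed chromatin sites, CTCF loci, motif hits and
#' the pruned timed GRN with centrality metrics, and (optionally) writes
#' the canonical exports. Every filtering step logs its in/out counts via
#' `message()`.
#'
#' @param scenario_dir directory holding `genome.fa`, `genes.gtf`,
#'   `ctcf.bed`, `peaks/`, `fpkm.csv`, `nanostring.csv`, `motifs.meme` and
#'   `scenario.json`.
#' @param config pipeline thresholds ([pipeline_config()]); default reads
#'   `scenario.json` from the scenario directory.
#' @param out_dir if non-NULL, exports are written here: `edges.tsv`,
#'   `metrics.tsv`, `profile.csv`, `sites.bed`, `loci.bed`, `hits.bed`,
#'   `biotapestry.csv`, `expression.xml`.
#' @return list with `profile`, `dropped`, `sites` (per-epoch indexed
#'   sites), `loci`, `site_hits`, `hits`, `grn` (pruned `timed_grn`),
#'   `metrics`, and `out_dir`.
#' @export
run_pipeline <- function(scenario_dir, config = NULL, out_dir = NULL) {
  if (is.null(config)) {
    cfg_path <- file.path(scenario_dir, "scenario.json")
    config <- if (file.exists(cfg_path))
      utils::modifyList(pipeline_config(),
                        jsonlite::read_json(cfg_path, simplifyVector = TRUE))
    else pipeline_config()
  }
  tps <- config$time_points
  cts <- sort(config$chip_times)

  ## expression
  fpkm <- read_fpkm(file.path(scenario_dir, "fpkm.csv"))
  rna <- rnaseq_calls(fpkm, times = intersect(c(0, cts), tps),
                      min_fpkm = config$min_fpkm, up_fc = config$up_fc,
                      down_fc = config$down_fc)
  nanostring <- read_nanostring(file.path(scenario_dir, "nanostring.csv"))
  nano <- nanostring_calls(nanostring, up = config$nano_up,
                           down = config$nano_down, alpha = config$alpha)
  integ <- integrate_platforms(rna, nano,
                               rnaseq_times = intersect(c(0, cts), tps),
                               nano_only_times = setdiff(tps, c(0, cts)))
  profile <- integ$profile
  grn_genes <- unique(profile$gene)
  message(sprintf("platform integration: %d gene(s) in, %d retained, %d dropped",
                  length(unique(rna$gene)), length(grn_genes),
                  nrow(integ$dropped)))

  ## chromatin
  sites_by_epoch <- list()
  for (ct in cts) {
    slots <- c("ac_induced", "me3_induced", "ac_uninduced", "me3_uninduced")
    raw <- lapply(slots, function(s)
      read_peak_table(file.path(scenario_dir, "peaks",
                                sprintf("%s_%gh.tsv", s, ct))))
    names(raw) <- slots
    filt <- lapply(raw, filter_enriched)
    message(sprintf("peak filter @%gh: %d in, %d retained", ct,
                    sum(vapply(raw, nrow, integer(1))),
                    sum(vapply(filt, nrow, integer(1)))))
    sites_by_epoch[[sprintf("%gh", ct)]] <-
      derive_indexed_sites(filt, ct, gap = config$merge_gap, filter = FALSE)
  }
  all_sites <- do.call(rbind, sites_by_epoch)
  rownames(all_sites) <- NULL

  ## loci
  genes <- read_gtf_genes(file.path(scenario_dir, "genes.gtf"))
  genes <- genes[genes$gene_id %in% grn_genes, , drop = FALSE]
  ctcf <- read_ctcf_bed(file.path(scenario_dir, "ctcf.bed"))
  loci <- build_loci(genes, ctcf, max_search = config$max_search)

  ## candidate sites per gene (mode selection), unique sequences, motif hits
  selected <- sites_for_network(all_sites, mode = config$mode)
  message(sprintf("site selection (%s): %d site-epoch(s) in, %d selected",
                  config$mode, nrow(all_sites), nrow(selected)))
  owned <- do.call(rbind, lapply(seq_len(nrow(loci)), function(i)
    sites_in_locus(loci[i, ], selected)))
  if (is.null(owned)) owned <- cbind(gene_id = character(), selected[0, ])
  owned$site_id <- sprintf("%s:%d-%d@%gh", owned$chrom, owned$start,
                           owned$end, owned$chip_time)
  owned$coord_key <- sprintf("%s:%d-%d", owned$chrom, owned$start, owned$end)

  genome <- read_genome(file.path(scenario_dir, "genome.fa"))
  pwms <- load_motifs(file.path(scenario_dir, "motifs.meme"),
                      gene_ids = grn_genes)
  uniq <- owned[!duplicated(owned$coord_key), , drop = FALSE]
  hits <- if (nrow(uniq)) {
    seqs <- extract_sequences(uniq, genome)
    uniq_sites <- data.frame(site_id = uniq$coord_key, chrom = uniq$chrom,
                             start = uniq$start, end = uniq$end,
                             stringsAsFactors = FALSE)
    hits_for_gene(uniq_sites, seqs, pwms, grn_genes,
                  threshold = config$score_threshold)
  } else {
    hits_for_gene(data.frame(site_id = character(), chrom = character(),
                             start = integer(), end = integer()),
                  Biostrings::DNAStringSet(), pwms, grn_genes)
  }
  message(sprintf("motif scan: %d unique site(s), %d hit(s) above score %s",
                  nrow(uniq), nrow(hits), config$score_threshold))

  ## site-hit table for the builder
  site_hits <- merge(
    owned[, c("gene_id", "site_id", "coord_key", "chip_time", "index")],
    hits[, c("site_id", "tf_gene")], by.x = "coord_key", by.y = "site_id")
  site_hits <- data.frame(
    target_gene = site_hits$gene_id, site_id = site_hits$site_id,
    chip_time = site_hits$chip_time,
    site_class = ifelse(site_hits$index %in% c(1:3, 7), "activation",
                        "repression"),
    tf_gene = site_hits$tf_gene, stringsAsFactors = FALSE)
  site_hits <- site_hits[!duplicated(site_hits), , drop = FALSE]

  grn <- build_grn(profile, site_hits, grn_genes, time_points = tps,
                   chip_times = cts)
  grn <- prune_isolated(grn)
  message(sprintf("network: %d interaction(s), %d gene(s) retained, %d pruned",
                  nrow(grn$edges), length(grn$genes), length(grn$pruned)))
  metrics <- grn_metrics(grn)

  result <- list(profile = profile, dropped = integ$dropped,
                 sites = all_sites, loci = loci, site_hits = site_hits,
                 hits = hits, owned_sites = owned, grn = grn,
                 metrics = metrics, config = config, out_dir = out_dir)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(grn$edges, file.path(out_dir, "edges.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(metrics, file.path(out_dir, "metrics.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.csv(profile, file.path(out_dir, "profile.csv"),
                     row.names = FALSE, quote = FALSE)
    export_bed(data.frame(chrom = all_sites$chrom, start = all_sites$start,
                          end = all_sites$end,
                          name = sprintf("index%d@%gh", all_sites$index,
                                         all_sites$chip_time),
                          score = all_sites$index,
                          stringsAsFactors = FALSE),
               file.path(out_dir, "sites.bed"), "indexed_sites")
    export_bed(data.frame(chrom = loci$chrom, start = loci$locus_start,
                          end = loci$locus_end, name = loci$gene_id,
                          stringsAsFactors = FALSE),
               file.path(out_dir, "loci.bed"), "regulatory_loci")
    export_bed(if (nrow(hits))
                 data.frame(chrom = sub(":.*", "", hits$site_id),
                            start = hits$genomic_start,
                            end = hits$genomic_end,
                            name = sprintf("%s_%s", hits$tf_gene,
                                           hits$motif_id),
                            score = round(hits$score, 3),
                            strand = hits$strand, stringsAsFactors = FALSE)
               else data.frame(chrom = character(), start = integer(),
                               end = integer()),
               file.path(out_dir, "hits.bed"), "tfbs_hits")
    export_biotapestry(grn, file.path(out_dir, "biotapestry.csv"),
                       file.path(out_dir, "expression.xml"))
  }
  result
}

#' Compare a pipeline edge set against a planted truth
#'
#' Precision/recall on the (regulator, target, sign, time) tuples.
#'
#' @param edges pipeline edge data.frame.
#' @param truth_edges ground-truth edge data.frame with the same columns.
#' @return list `precision`, `recall`, `n_found`, `n_truth`,
#'   `false_positives`, `false_negatives`.
#' @export
edge_recovery <- function(edges, truth_edges) {
  key <- function(e) if (nrow(e))
    paste(e$regulator, e$target, e$sign, e$time) else character()
  found <- key(edges)
  truth <- key(truth_edges)
  tp <- sum(found %in% truth)
  list(precision = if (length(found)) tp / length(found) else 1,
       recall = if (length(truth)) sum(truth %in% found) / length(truth)
                else 1,
       n_found = length(found), n_truth = length(truth),
       false_positives = setdiff(found, truth),
       false_negatives = setdiff(truth, found))
}
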