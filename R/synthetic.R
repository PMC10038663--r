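# Synthetic-data module: a complete, internally consistent toy induction
# time course with a planted ground-truth network. Every file the pipeline
# consumes is generated here; the planted edges are re-derivable through the
# real pipeline (zero noise -> exact recovery). Layout constants below are
# per-locus tile offsets in bp; they assume tile_bp >= 10000.

TILE_MIN <- 10000L
TILE_CTCF_UP <- c(1000L, 1200L)
TILE_CTCF_DECOY <- c(1600L, 1760L)
TILE_SITE_STARTS <- c(2000L, 2600L, 3200L)
TILE_SITE_WIDTH <- 240L
TILE_GENE <- c(4200L, 6200L)
TILE_CTCF_DOWN <- c(8800L, 9000L)
TILE_MAX_SEARCH <- 4000L

#' Scenario configuration for the synthetic generator
#'
#' Defaults describe the stated world of the package's validation suite: a
#' desk-scale induction time course (7 expression time points, 3 ChIP
#' epochs, triplicate NanoString lanes with 6 positive / 8 negative / 2
#' housekeeping probes) whose loci tile a 10 kb grid; the per-side CTCF
#' search window is scaled accordingly (4 kb standing in for 500 kb).
#'
#' @param n_genes number of genes including decoys (>= 2; default 24).
#' @param n_decoy_genes genes with no expression change and no planted
#'   regulation, expected to be pruned (default 2).
#' @param tile_bp per-gene tile width in bp (>= 10000).
#' @param time_points expression time points in hours.
#' @param chip_times ChIP epochs in hours.
#' @param n_planted_edges number of planted regulator-site relationships;
#'   default (`NULL`) is one per non-decoy gene, arranged as a ring ordered
#'   by expression onset so that every non-decoy gene has at least one
#'   interaction.
#' @param motif_length planted motif length in bp (>= 6 so that an exact
#'   consensus clears the score cutoff of 10).
#' @param noise_sd log-normal SD of FPKM noise; also gates Poisson counting
#'   noise on the NanoString counts (0 = fully deterministic world).
#' @param lane_scale_range range of the uniform per-lane scale factors.
#' @param gc background GC content (default 0.5).
#' @param decoys_per_site number of decoy motifs (unmapped TF) planted per
#'   relationship site (default 0).
#' @param seed integer seed; fully determines the bundle.
#' @return a `scenario_config` list.
#' @export
scenario_config <- function(n_genes = 24, n_decoy_genes = 2,
                            tile_bp = 10000,
                            time_points = c(0, 1, 3, 5, 7, 9, 12),
                            chip_times = c(5, 9, 12),
                            n_planted_edges = NULL, motif_length = 12,
                            noise_sd = 0.1, lane_scale_range = c(0.7, 1.4),
                            gc = 0.5, decoys_per_site = 0, seed = 1) {
  if (n_genes < 2) stop("n_genes must be >= 2")
  if (n_decoy_genes >= n_genes - 1)
    stop("need at least two non-decoy genes")
  if (tile_bp < TILE_MIN)
    stop(sprintf(
      "tile_bp = %d cannot place a locus: the fixed layout (CTCF flanks, 3 sites, gene body) needs >= %d bp per gene",
      tile_bp, TILE_MIN))
  if (motif_length < 6)
    stop("motif_length must be >= 6 for a consensus hit to clear score 10")
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  structure(list(n_genes = as.integer(n_genes),
                 n_decoy_genes = as.integer(n_decoy_genes),
                 tile_bp = as.integer(tile_bp),
                 time_points = time_points, chip_times = chip_times,
                 n_planted_edges = n_planted_edges,
                 motif_length = as.integer(motif_length),
                 noise_sd = noise_sd, lane_scale_range = lane_scale_range,
                 gc = gc, decoys_per_site = as.integer(decoys_per_site),
                 seed = as.integer(seed)),
            class = "scenario_config")
}

#' Pipeline thresholds matched to a scenario
#'
#' @param max_search CTCF search window per side (bp).
#' @param time_points,chip_times time grids.
#' @param min_fpkm,up_fc,down_fc RNA-seq call thresholds.
#' @param nano_up,nano_down,alpha NanoString call thresholds.
#' @param score_threshold motif score cutoff.
#' @param merge_gap site merge gap (bp); `subnet_gap` the cross-epoch
#'   subnetwork merge gap.
#' @param mode site-selection mode for the main network.
#' @return a named list of thresholds consumed by [run_pipeline()].
#' @export
pipeline_config <- function(max_search = 500000,
                            time_points = c(0, 1, 3, 5, 7, 9, 12),
                            chip_times = c(5, 9, 12), min_fpkm = 10,
                            up_fc = 1.5, down_fc = 0.5, nano_up = 1.2,
                            nano_down = 0.8, alpha = 0.05,
                            score_threshold = 10, merge_gap = 100,
                            subnet_gap = 500, mode = "activation_only") {
  list(max_search = max_search, time_points = time_points,
       chip_times = chip_times, min_fpkm = min_fpkm, up_fc = up_fc,
       down_fc = down_fc, nano_up = nano_up, nano_down = nano_down,
       alpha = alpha, score_threshold = score_threshold,
       merge_gap = merge_gap, subnet_gap = subnet_gap, mode = mode)
}

# Intended direction of gene g at time t (the generator's ground truth).
# Class "pre" (onset 0): expressed before induction, repressed afterwards.
# Class "up" with onset tau: none before tau, up from tau on.
# Class "decoy": never called.
truth_direction <- function(class, onset, t) {
  if (class == "decoy") return("none")
  if (class == "pre") return(if (t == 0) "up" else "down")
  if (t >= onset && t > 0) "up" else "none"
}

#' Substitute a PWM consensus into a sequence
#'
#' The motif window starting at `offset` (0-based) is replaced by the PWM
#' consensus, reverse-complemented for minus-strand plants; the rest of the
#' sequence is untouched. Scanning the planted window scores the PWM
#' maximum.
#'
#' @param sequence character scalar.
#' @param pwm a [new_pwm()] object.
#' @param offset 0-based plant position.
#' @param strand `"+"` or `"-"`.
#' @return the modified sequence.
#' @export
plant_motif <- function(sequence, pwm, offset, strand = "+") {
  L <- ncol(pwm$counts)
  n <- nchar(sequence)
  if (offset < 0 || offset + L > n)
    stop(sprintf("offset %d out of range for motif length %d in %d bp",
                 offset, L, n))
  ins <- pwm_consensus(pwm)
  if (strand == "-") ins <- revcomp(ins)
  paste0(substr(sequence, 1, offset), ins,
         substr(sequence, offset + L + 1, n))
}

random_consensus <- function(L, taken) {
  repeat {
    s <- paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
               collapse = "")
    # palindromes are rejected so a plant on one strand is never a chance
    # occurrence on the other
    if (!s %in% taken && !revcomp(s) %in% taken && revcomp(s) != s)
      return(s)
  }
}

consensus_pwm <- function(motif_id, tf, consensus) {
  L <- nchar(consensus)
  counts <- matrix(1, 4, L, dimnames = list(c("A", "C", "G", "T"), NULL))
  idx <- match(strsplit(consensus, "")[[1]], c("A", "C", "G", "T"))
  counts[cbind(idx, seq_len(L))] <- 99997
  new_pwm(motif_id, tf, counts)
}

# Site index trajectory over the three ChIP epochs, cycled over
# relationship serials; all are activation-class (indices 1,2,3,7) at every
# epoch so the planted edge is available whenever expression allows it.
REL_SITE_PATTERNS <- list(c(1, 1, 1), c(2, 2, 2), c(7, 7, 7), c(3, 1, 1))
# Unused sites alternate a repression trajectory and silence.
UNUSED_SITE_PATTERNS <- list(c(4, 5, 6), NULL)

#' Generate a complete synthetic scenario
#'
#' Writes genome FASTA, gene GTF, CTCF BED, per-mark/condition/epoch peak
#' tables, an FPKM table, triplicate NanoString assays, a MEME motif
#' library, the ground truth, and a matched pipeline configuration
#' (`scenario.json`) into `dir`. Re-running with the same config yields
#' byte-identical files.
#'
#' The bundle is mutually consistent: planted motif instances are literally
#' present in the genome at their recorded offsets; any *chance* occurrence
#' of a library consensus inside a regulatory site is destroyed by a
#' deterministic single-base edit, so at zero noise the pipeline recovers
#' exactly the planted edge set. Sub-threshold decoy peaks (failing the
#' enrichment filter) and a low-signal decoy CTCF peak are planted to
#' exercise the corresponding filters.
#'
#' @param config a [scenario_config()].
#' @param dir output directory (created if needed).
#' @return invisible list: `dir`, `config`, `pipeline_config`, `genome`,
#'   `genes`, `ctcf`, `peaks` (nested list by epoch), `fpkm`, `nanostring`,
#'   `pwms`, and `truth` (list with `edges`, `relationships`, `sites`,
#'   `motifs`).
#' @export
generate_scenario <- function(config = scenario_config(), dir = tempfile()) {
  stopifnot(inherits(config, "scenario_config"))
  set.seed(config$seed)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  dir.create(file.path(dir, "peaks"), showWarnings = FALSE)

  n <- config$n_genes
  nd <- config$n_decoy_genes
  tile <- config$tile_bp
  tps <- config$time_points
  cts <- sort(config$chip_times)

  ## --- genes: two chromosomes, tiled loci ---------------------------------
  gene_ids <- sprintf("GENE%02d", seq_len(n))
  chrom_of <- ifelse(seq_len(n) <= ceiling(n / 2), "chr1", "chr2")
  tile_idx <- ave(seq_len(n), chrom_of, FUN = seq_along) - 1L
  tile0 <- tile_idx * tile
  genes <- data.frame(gene_id = gene_ids, chrom = chrom_of,
                      start = tile0 + TILE_GENE[1], end = tile0 + TILE_GENE[2],
                      strand = "+", stringsAsFactors = FALSE)

  # classes and onsets: decoys last; the rest cycle through the onsets
  onset_cycle <- tps[-1]  # 1,3,5,7,9,12
  classes <- character(n)
  onsets <- numeric(n)
  k <- 0L
  for (i in seq_len(n)) {
    if (i > n - nd) { classes[i] <- "decoy"; onsets[i] <- NA; next }
    slot <- k %% (length(onset_cycle) + 1L)
    if (slot == 0L) { classes[i] <- "pre"; onsets[i] <- 0 }
    else { classes[i] <- "up"; onsets[i] <- onset_cycle[slot] }
    k <- k + 1L
  }

  ## --- genome -------------------------------------------------------------
  chrom_len <- vapply(c("chr1", "chr2"), function(ch)
    (sum(chrom_of == ch)) * tile, numeric(1))
  probs <- c((1 - config$gc) / 2, config$gc / 2, config$gc / 2,
             (1 - config$gc) / 2)
  chrom_seq <- lapply(chrom_len, function(len)
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE, prob = probs),
          collapse = ""))

  ## --- CTCF peaks ---------------------------------------------------------
  ctcf <- do.call(rbind, lapply(seq_len(n), function(i) {
    t0 <- tile0[i]
    data.frame(chrom = chrom_of[i],
               start = t0 + c(TILE_CTCF_UP[1], TILE_CTCF_DECOY[1],
                              TILE_CTCF_DOWN[1]),
               end = t0 + c(TILE_CTCF_UP[2], TILE_CTCF_DECOY[2],
                            TILE_CTCF_DOWN[2]),
               name = sprintf("ctcf_%s_%s", gene_ids[i],
                              c("up", "decoy", "down")),
               score = 0, strand = ".", signal = c(50, 5, 50),
               stringsAsFactors = FALSE)
  }))

  ## --- sites --------------------------------------------------------------
  sites <- do.call(rbind, lapply(seq_len(n), function(i) {
    s <- tile0[i] + TILE_SITE_STARTS
    data.frame(gene_id = gene_ids[i], site_serial = seq_along(s),
               chrom = chrom_of[i], start = s, end = s + TILE_SITE_WIDTH,
               stringsAsFactors = FALSE)
  }))
  sites$site_key <- sprintf("%s:%d-%d", sites$chrom, sites$start, sites$end)

  ## --- relationships (planted regulator -> target through a site) --------
  nondecoy <- which(classes != "decoy")
  ring <- nondecoy[order(ifelse(classes[nondecoy] == "pre", 0,
                                onsets[nondecoy]), nondecoy)]
  n_rel <- if (is.null(config$n_planted_edges)) length(ring)
           else config$n_planted_edges
  rel <- list()
  if (n_rel > 0) {
    # ring R_k -> T_{k+1}, then second-neighbour chords for extras
    hop <- 1L
    used_per_target <- stats::setNames(integer(length(gene_ids)), gene_ids)
    while (length(rel) < n_rel) {
      for (k in seq_along(ring)) {
        if (length(rel) >= n_rel) break
        R <- gene_ids[ring[k]]
        Tg <- gene_ids[ring[(k - 1L + hop) %% length(ring) + 1L]]
        serial <- used_per_target[Tg] %% 3L + 1L
        slot <- used_per_target[Tg] %/% 3L  # offset slot when sites reused
        used_per_target[Tg] <- used_per_target[Tg] + 1L
        rel[[length(rel) + 1L]] <- list(regulator = R, target = Tg,
                                        site_serial = serial,
                                        offset_slot = slot)
      }
      hop <- hop + 1L
      if (hop > length(ring)) break
    }
  }

  ## --- motif library ------------------------------------------------------
  regulators <- unique(vapply(rel, `[[`, "", "regulator"))
  taken <- character()
  pwms <- list()
  for (r in regulators) {
    cons <- random_consensus(config$motif_length, taken)
    taken <- c(taken, cons)
    pwms[[r]] <- consensus_pwm(sprintf("M%03d", match(r, gene_ids)), r, cons)
  }
  decoy_pwms <- list()
  if (config$decoys_per_site > 0) {
    for (d in seq_len(config$decoys_per_site)) {
      cons <- random_consensus(config$motif_length, taken)
      taken <- c(taken, cons)
      decoy_pwms[[d]] <- consensus_pwm(sprintf("D%03d", d),
                                       sprintf("DECOYTF%d", d), cons)
    }
  }

  ## --- plant motifs into the genome --------------------------------------
  plant_offsets <- function(slot) 20L + slot * (config$motif_length + 18L)
  planted <- list()  # site_key -> data.frame(offset, strand, consensus)
  add_plant <- function(site_row, offset, strand, pwm) {
    ch <- site_row$chrom
    pos0 <- site_row$start + offset  # genome 0-based
    cons <- pwm_consensus(pwm)
    ins <- if (strand == "-") revcomp(cons) else cons
    seq <- chrom_seq[[ch]]
    chrom_seq[[ch]] <<- paste0(substr(seq, 1, pos0), ins,
                               substr(seq, pos0 + nchar(ins) + 1,
                                      nchar(seq)))
    key <- site_row$site_key
    planted[[key]] <<- rbind(planted[[key]], data.frame(
      offset = offset, strand = strand, consensus = cons,
      motif_id = pwm$motif_id, tf = pwm$tf, stringsAsFactors = FALSE))
  }
  rel_site_row <- function(r) {
    sites[sites$gene_id == r$target & sites$site_serial == r$site_serial, ]
  }
  for (j in seq_along(rel)) {
    r <- rel[[j]]
    srow <- rel_site_row(r)
    off <- plant_offsets(r$offset_slot)
    if (off + config$motif_length > TILE_SITE_WIDTH - 30L)
      stop("too many relationships per site: motif placement overflows")
    strand <- if (j %% 2L == 0L) "-" else "+"
    add_plant(srow, off, strand, pwms[[r$regulator]])
    rel[[j]]$offset <- off
    rel[[j]]$strand <- strand
    rel[[j]]$site_key <- srow$site_key
  }
  if (length(decoy_pwms)) {
    rel_keys <- unique(vapply(rel, `[[`, "", "site_key"))
    for (key in rel_keys) {
      srow <- sites[sites$site_key == key, ]
      for (d in seq_along(decoy_pwms))
        add_plant(srow, TILE_SITE_WIDTH - 20L -
                    d * (config$motif_length + 6L), "+", decoy_pwms[[d]])
    }
  }

  ## --- destroy chance consensus occurrences inside sites ------------------
  all_pwms <- c(unname(pwms), decoy_pwms)
  all_cons <- vapply(all_pwms, pwm_consensus, character(1))
  L <- config$motif_length
  for (pass in seq_len(20L)) {
    dirty <- FALSE
    for (i in seq_len(nrow(sites))) {
      key <- sites$site_key[i]
      ch <- sites$chrom[i]
      sseq <- substr(chrom_seq[[ch]], sites$start[i] + 1L, sites$end[i])
      pl <- planted[[key]]
      for (m in seq_along(all_cons)) {
        for (strand in c("+", "-")) {
          pat <- if (strand == "+") all_cons[m] else revcomp(all_cons[m])
          occ <- gregexpr(pat, sseq, fixed = TRUE)[[1]]
          if (occ[1] == -1) next
          for (o in occ) {
            off <- o - 1L
            ok <- !is.null(pl) && any(pl$offset == off & pl$strand == strand &
                                        pl$consensus == all_cons[m])
            if (ok) next
            # deterministic edit at the first window position not covered
            # by a planted instance
            covered <- rep(FALSE, L)
            if (!is.null(pl)) {
              for (q in seq_len(nrow(pl))) {
                lo <- pl$offset[q] - off + 1L
                hi <- lo + L - 1L
                idx <- max(1L, lo):min(L, hi)
                if (length(idx) && lo <= L && hi >= 1L)
                  covered[idx[idx >= 1 & idx <= L]] <- TRUE
              }
            }
            p_rel <- which(!covered)[1]
            if (is.na(p_rel)) stop("cannot break chance motif occurrence")
            gpos <- sites$start[i] + off + p_rel  # 1-based genome position
            cur <- substr(chrom_seq[[ch]], gpos, gpos)
            repl <- setdiff(c("A", "C", "G", "T"), cur)[1]
            substr(chrom_seq[[ch]], gpos, gpos) <- repl
            dirty <- TRUE
          }
        }
      }
    }
    if (!dirty) break
    if (pass == 20L) stop("could not sanitize site sequences in 20 passes")
  }

  ## --- site state patterns and ChIP peaks ---------------------------------
  itab <- chromatin_index_table()
  rel_serials <- unique(vapply(rel, function(r)
    paste(r$target, r$site_serial), character(1)))
  site_pattern <- vector("list", nrow(sites))
  rel_ct <- 0L; un_ct <- 0L
  for (i in seq_len(nrow(sites))) {
    id <- paste(sites$gene_id[i], sites$site_serial[i])
    if (id %in% rel_serials) {
      rel_ct <- rel_ct + 1L
      site_pattern[i] <- REL_SITE_PATTERNS[(rel_ct - 1L) %%
                                             length(REL_SITE_PATTERNS) + 1L]
    } else {
      un_ct <- un_ct + 1L
      site_pattern[i] <- UNUSED_SITE_PATTERNS[(un_ct - 1L) %%
                                                length(UNUSED_SITE_PATTERNS) + 1L]
    }
  }

  peak_sets <- list()
  for (e in seq_along(cts)) {
    sets <- list(ac_induced = list(), me3_induced = list(),
                 ac_uninduced = list(), me3_uninduced = list())
    for (i in seq_len(nrow(sites))) {
      pat <- site_pattern[[i]]
      if (is.null(pat)) next
      row <- itab[itab$index == pat[e], ]
      for (cond in c("induced", "uninduced")) {
        status <- if (cond == "induced") row$induced else row$uninduced
        marks <- switch(status, none = character(), ac = "ac", me3 = "me3",
                        both = c("ac", "me3"))
        for (mk in marks) {
          slot <- paste(mk, cond, sep = "_")
          sets[[slot]][[length(sets[[slot]]) + 1L]] <- data.frame(
            chrom = sites$chrom[i], start = sites$start[i],
            end = sites$end[i],
            name = sprintf("%s_%s_%dh", sites$site_key[i], slot, cts[e]),
            score = 100, strand = ".", signal = 20, p_score = 8,
            q_score = 6, fold_change = 2.5, stringsAsFactors = FALSE)
        }
      }
    }
    # sub-threshold decoys: would corrupt the state if the enrichment
    # filter were skipped (me3 on an active site -> poised -> edge lost)
    for (i in which(vapply(site_pattern, function(p)
      !is.null(p) && p[e] %in% c(1:3, 7), logical(1)))) {
      sets$me3_induced[[length(sets$me3_induced) + 1L]] <- data.frame(
        chrom = sites$chrom[i], start = sites$start[i], end = sites$end[i],
        name = sprintf("%s_decoy_%dh", sites$site_key[i], cts[e]),
        score = 10, strand = ".", signal = 2, p_score = 3, q_score = 1,
        fold_change = 1.1, stringsAsFactors = FALSE)
    }
    peak_sets[[sprintf("%gh", cts[e])]] <- lapply(sets, function(s)
      if (length(s)) do.call(rbind, s)
      else data.frame(chrom = character(), start = integer(),
                      end = integer(), name = character(), score = numeric(),
                      strand = character(), signal = numeric(),
                      p_score = numeric(), q_score = numeric(),
                      fold_change = numeric(), stringsAsFactors = FALSE))
  }

  ## --- expression tables ---------------------------------------------------
  noisy <- function(mean) {
    if (config$noise_sd == 0) mean
    else mean * exp(stats::rnorm(length(mean), 0, config$noise_sd))
  }
  fpkm_mean <- function(i, cond, t) {
    cl <- classes[i]; on <- onsets[i]
    if (cl == "decoy") return(5)
    if (cl == "pre") {
      if (cond == "uninduced") return(30)
      return(5)                      # induced: repressed after the graft
    }
    # "up" class
    if (cond == "induced" && t >= on) return(30)
    5
  }
  samples <- c("uninduced_0h", "induced_5h", "uninduced_5h", "induced_9h",
               "uninduced_9h", "induced_12h", "uninduced_12h")
  fpkm <- data.frame(gene = gene_ids, stringsAsFactors = FALSE)
  for (s in samples) {
    parts <- strsplit(s, "_")[[1]]
    cond <- parts[1]
    t <- as.numeric(sub("h", "", parts[2]))
    fpkm[[s]] <- round(noisy(vapply(seq_len(n), fpkm_mean, numeric(1),
                                    cond = cond, t = t)), 4)
  }

  ## --- NanoString ----------------------------------------------------------
  nano_times <- setdiff(tps, 0)
  pos_base <- c(800, 400, 200, 100, 50, 25)
  neg_base <- rep(12, 8)
  hk_base <- c(2000, 1500)
  endo_mean <- function(i, cond, t) {
    cl <- classes[i]; on <- onsets[i]
    if (cl == "decoy") return(500)
    if (cl == "pre") return(if (cond == "induced") 250 else 500)
    if (cond == "induced" && t >= on) return(1000)
    500
  }
  nano_rows <- list()
  for (t in nano_times) for (cond in c("induced", "uninduced"))
    for (rep_i in 1:3) {
      lane <- stats::runif(1, config$lane_scale_range[1],
                           config$lane_scale_range[2])
      assay <- sprintf("%s_%gh_r%d", cond, t, rep_i)
      probe <- c(sprintf("POS_%s", LETTERS[1:6]),
                 sprintf("NEG_%s", LETTERS[1:8]), "HK_ACTB", "HK_GAPDH",
                 gene_ids)
      class_col <- c(rep("positive", 6), rep("negative", 8),
                     rep("housekeeping", 2), rep("endogenous", n))
      mean_ct <- c(pos_base, neg_base, hk_base,
                   vapply(seq_len(n), endo_mean, numeric(1), cond = cond,
                          t = t)) * lane
      count <- if (config$noise_sd == 0) mean_ct
               else stats::rpois(length(mean_ct), mean_ct)
      nano_rows[[length(nano_rows) + 1L]] <- data.frame(
        assay = assay, condition = cond, time = t, replicate = rep_i,
        probe = probe, class = class_col, count = count,
        fields_of_view = 600, binding_density = 1.0,
        stringsAsFactors = FALSE)
    }
  nanostring <- do.call(rbind, nano_rows)

  ## --- ground-truth edge set (forward model of the rule table) ------------
  dir_of <- function(i, t) truth_direction(classes[i], onsets[i], t)
  reg_dir_of <- function(i, t) {
    d <- dir_of(i, t)
    if (d != "none") return(d)
    earlier <- tps[tps < t]
    if (!length(earlier)) return("none")
    dir_of(i, max(earlier))
  }
  truth_edges <- list()
  for (t in tps) {
    e_idx <- which(cts == chip_epoch(t, cts, tps))
    for (r in rel) {
      srow_i <- which(sites$gene_id == r$target &
                        sites$site_serial == r$site_serial)
      pat <- site_pattern[[srow_i]]
      if (is.null(pat) || !pat[e_idx] %in% c(1:3, 7)) next
      ti <- match(r$target, gene_ids)
      ri <- match(r$regulator, gene_ids)
      td <- dir_of(ti, t)
      if (td == "none") next
      rd <- reg_dir_of(ri, t)
      if (rd == "none") next
      sign <- if (rd == td) "positive" else "negative"
      truth_edges[[length(truth_edges) + 1L]] <- data.frame(
        regulator = r$regulator, target = r$target, sign = sign, time = t,
        site_key = r$site_key, stringsAsFactors = FALSE)
    }
  }
  truth_edges <- if (length(truth_edges)) do.call(rbind, truth_edges)
                 else data.frame(regulator = character(),
                                 target = character(), sign = character(),
                                 time = numeric(), site_key = character(),
                                 stringsAsFactors = FALSE)
  truth_edges <- truth_edges[!duplicated(truth_edges[, c("regulator",
                                                         "target", "sign",
                                                         "time")]), ]
  truth_edges <- truth_edges[order(truth_edges$time, truth_edges$regulator,
                                   truth_edges$target), ]
  rownames(truth_edges) <- NULL

  truth_sites <- do.call(rbind, lapply(seq_len(nrow(sites)), function(i) {
    pat <- site_pattern[[i]]
    if (is.null(pat)) return(NULL)
    data.frame(gene_id = sites$gene_id[i], site_key = sites$site_key[i],
               chip_time = cts, index = pat, stringsAsFactors = FALSE)
  }))
  truth_motifs <- do.call(rbind, lapply(rel, function(r) data.frame(
    site_key = r$site_key, regulator = r$regulator, offset = r$offset,
    strand = r$strand, stringsAsFactors = FALSE)))

  ## --- write files ---------------------------------------------------------
  genome <- Biostrings::DNAStringSet(unlist(chrom_seq))
  names(genome) <- names(chrom_seq)
  write_genome(genome, file.path(dir, "genome.fa"))
  write_gtf_genes(genes, file.path(dir, "genes.gtf"))
  write_ctcf_bed(ctcf, file.path(dir, "ctcf.bed"))
  for (e in names(peak_sets))
    for (slot in names(peak_sets[[e]]))
      write_peak_table(peak_sets[[e]][[slot]],
                       file.path(dir, "peaks",
                                 sprintf("%s_%s.tsv", slot, e)))
  utils::write.csv(fpkm, file.path(dir, "fpkm.csv"), row.names = FALSE,
                   quote = FALSE)
  utils::write.csv(nanostring, file.path(dir, "nanostring.csv"),
                   row.names = FALSE, quote = FALSE)
  write_meme(all_pwms, file.path(dir, "motifs.meme"))
  utils::write.csv(truth_edges, file.path(dir, "truth_edges.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(truth_sites, file.path(dir, "truth_sites.csv"),
                   row.names = FALSE, quote = FALSE)
  if (!is.null(truth_motifs))
    utils::write.csv(truth_motifs, file.path(dir, "truth_motifs.csv"),
                     row.names = FALSE, quote = FALSE)
  pcfg <- pipeline_config(max_search = TILE_MAX_SEARCH,
                          time_points = tps, chip_times = cts)
  jsonlite::write_json(pcfg, file.path(dir, "scenario.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(dir = dir, config = config, pipeline_config = pcfg,
                 genome = genome, genes = genes, ctcf = ctcf,
                 peaks = peak_sets, fpkm = fpkm, nanostring = nanostring,
                 pwms = all_pwms,
                 truth = list(edges = truth_edges,
                              relationships = rel, sites = truth_sites,
                              motifs = truth_motifs,
                              classes = stats::setNames(classes, gene_ids),
                              onsets = stats::setNames(onsets, gene_ids))))
}
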