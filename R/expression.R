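#' Direction call from paired FPKM values
#'
#' Applies the RNA-seq fold-change rules: a gene is *up* at a time point when
#' its induced FPKM exceeds `min_fpkm` and the induced/uninduced fold change
#' exceeds `up_fc`; *down* when the uninduced FPKM exceeds `min_fpkm` and the
#' fold change is below `down_fc`; otherwise *none*. A zero uninduced value
#' makes the fold change +Inf, which can only take the up path.
#'
#' @param fpkm_induced,fpkm_uninduced non-negative FPKM vectors.
#' @param up_fc,down_fc,min_fpkm thresholds (defaults 1.5, 0.5, 10).
#' @return character vector in `up`, `down`, `none`.
#' @examples
#' classify_fpkm(20, 10)  # "up"
#' classify_fpkm(9, 3)    # "none": abundance gate fails
#' classify_fpkm(5, 20)   # "down"
#' @export
classify_fpkm <- function(fpkm_induced, fpkm_uninduced, up_fc = 1.5,
                          down_fc = 0.5, min_fpkm = 10) {
  if (any(fpkm_induced < 0) || any(fpkm_uninduced < 0))
    stop("FPKM values must be non-negative")
  fc <- ifelse(fpkm_uninduced == 0, Inf, fpkm_induced / fpkm_uninduced)
  up <- fpkm_induced > min_fpkm & fc > up_fc
  down <- fpkm_uninduced > min_fpkm & fc < down_fc
  ifelse(up, "up", ifelse(down, "down", "none"))
}

#' Direction call at the 0 h time point
#'
#' The 0 h sample exists only for uninduced tissue, so expression at time
#' zero is called by comparing the 0 h uninduced value against the 5 h
#' induced tissue: *up* iff the 0 h uninduced FPKM exceeds 10, its ratio to
#' the 5 h induced FPKM exceeds 1.5, and the 5 h uninduced FPKM both exceeds
#' 10 and exceeds the 5 h induced value. Anything else is *none*. A zero 5 h
#' induced value makes the ratio +Inf.
#'
#' @param unind_0h,ind_5h,unind_5h non-negative FPKM vectors.
#' @return character vector in `up`, `none`.
#' @export
classify_time_zero <- function(unind_0h, ind_5h, unind_5h) {
  if (any(unind_0h < 0) || any(ind_5h < 0) || any(unind_5h < 0))
    stop("FPKM values must be non-negative")
  ratio <- ifelse(ind_5h == 0, Inf, unind_0h / ind_5h)
  up <- unind_0h > 10 & ratio > 1.5 & unind_5h > 10 & unind_5h > ind_5h
  ifelse(up, "up", "none")
}

#' Candidate selection from differential-expression rows
#'
#' Stringent probe-set selection: up-candidates need log2 fold change >= 1.2,
#' p < 0.05 and induced base mean >= 45; down-candidates need log2 fold
#' change <= -1.2, p < 0.05 and uninduced base mean >= 200.
#'
#' @param log2_fc,p_value,induced_base_mean,uninduced_base_mean numeric
#'   vectors (recycled).
#' @return character vector in `up-candidate`, `down-candidate`, `rejected`.
#' @export
select_candidates <- function(log2_fc, p_value, induced_base_mean,
                              uninduced_base_mean) {
  if (any(p_value < 0 | p_value > 1)) stop("p-values must lie in [0, 1]")
  up <- log2_fc >= 1.2 & p_value < 0.05 & induced_base_mean >= 45
  down <- log2_fc <= -1.2 & p_value < 0.05 & uninduced_base_mean >= 200
  ifelse(up, "up-candidate", ifelse(down, "down-candidate", "rejected"))
}

geomean <- function(x) exp(mean(log(x)))

#' NanoString nCounter normalization
#'
#' Implements the two-factor lane normalization with background subtraction:
#'
#' 1. QC: assays must report 600 fields of view and a binding density within
#'    \[0.05, 2.25\]; failing assays are excluded (and listed in the result).
#' 2. PLNF (positive lane normalization factor): the arithmetic mean across
#'    assays of the geometric means of the six positive probes, divided by
#'    each assay's positive geomean. Negative, endogenous and housekeeping
#'    counts are multiplied by their assay's PLNF.
#' 3. LSNF (lane-specific normalization factor): computed identically from
#'    the housekeeping geomeans of the PLNF-scaled data, then applied to the
#'    negative and endogenous counts.
#' 4. Background: per assay, mean + 2 SD of its eight normalized negative
#'    probes, subtracted from the normalized endogenous counts; negative
#'    results are clipped to 0 and zeros are then replaced by 1.
#'
#' @param counts data.frame with columns `assay`, `probe`, `class`
#'   (`endogenous`, `positive`, `negative`, `housekeeping`), `count`, and
#'   optionally `fields_of_view` and `binding_density` per assay.
#' @return list with `endogenous` (probe x assay matrix of normalized
#'   counts), `plnf`, `lsnf`, `background` (named per assay), and `excluded`
#'   (data.frame of QC-failed assays with reasons).
#' @export
nanostring_normalize <- function(counts) {
  needed <- c("assay", "probe", "class", "count")
  missing <- setdiff(needed, names(counts))
  if (length(missing))
    stop("count table is missing column(s): ", paste(missing, collapse = ", "))
  counts$assay <- as.character(counts$assay)
  assays <- unique(counts$assay)

  excluded <- data.frame(assay = character(), reason = character(),
                         stringsAsFactors = FALSE)
  if (all(c("fields_of_view", "binding_density") %in% names(counts))) {
    for (a in assays) {
      sub <- counts[counts$assay == a, ]
      fov <- sub$fields_of_view[1]
      bd <- sub$binding_density[1]
      reason <- NULL
      if (!is.na(fov) && fov != 600) reason <- sprintf("fields_of_view=%s", fov)
      else if (!is.na(bd) && (bd < 0.05 || bd > 2.25))
        reason <- sprintf("binding_density=%s", bd)
      if (!is.null(reason)) {
        excluded <- rbind(excluded, data.frame(assay = a, reason = reason,
                                               stringsAsFactors = FALSE))
        message("excluding assay ", a, " (QC: ", reason, ")")
      }
    }
    assays <- setdiff(assays, excluded$assay)
    counts <- counts[counts$assay %in% assays, ]
  }
  if (!length(assays)) stop("no assay passed QC")
  for (cl in c("positive", "negative", "housekeeping", "endogenous"))
    if (!any(counts$class == cl)) stop("no probes of class '", cl, "'")

  get_mat <- function(cl) {
    sub <- counts[counts$class == cl, ]
    probes <- unique(sub$probe)
    m <- matrix(NA_real_, length(probes), length(assays),
                dimnames = list(probes, assays))
    m[cbind(match(sub$probe, probes), match(sub$assay, assays))] <- sub$count
    if (anyNA(m)) stop("probe class '", cl, "' is incomplete across assays")
    m
  }
  pos <- get_mat("positive")
  neg <- get_mat("negative")
  hk <- get_mat("housekeeping")
  endo <- get_mat("endogenous")

  pos_gm <- apply(pos, 2, geomean)
  if (any(pos_gm == 0)) stop("zero geometric mean among positive probes")
  plnf <- mean(pos_gm) / pos_gm
  neg <- sweep(neg, 2, plnf, `*`)
  hk <- sweep(hk, 2, plnf, `*`)
  endo <- sweep(endo, 2, plnf, `*`)

  hk_gm <- apply(hk, 2, geomean)
  if (any(hk_gm == 0)) stop("zero geometric mean among housekeeping probes")
  lsnf <- mean(hk_gm) / hk_gm
  neg <- sweep(neg, 2, lsnf, `*`)
  endo <- sweep(endo, 2, lsnf, `*`)

  background <- apply(neg, 2, function(x) mean(x) + 2 * stats::sd(x))
  endo <- sweep(endo, 2, background, `-`)
  endo[endo < 0] <- 0
  endo[endo == 0] <- 1

  list(endogenous = endo, plnf = plnf, lsnf = lsnf,
       background = background, excluded = excluded)
}

#' NanoString differential-expression call
#'
#' Fold change is the ratio of replicate means (induced/uninduced); the call
#' is *up* iff FC >= `up` and p <= `alpha`, *down* iff FC <= `down` and
#' p <= `alpha`, from a two-tailed equal-variance (Type 2) t-test on the
#' replicate counts. With zero pooled variance the test degenerates: p is 0
#' when the means differ and 1 when they are equal.
#'
#' @param induced,uninduced numeric replicate vectors (>= 2 each).
#' @param up,down,alpha thresholds (defaults 1.2, 0.8, 0.05).
#' @return list with `fc`, `p`, `direction`.
#' @export
nanostring_de <- function(induced, uninduced, up = 1.2, down = 0.8,
                          alpha = 0.05) {
  if (length(induced) < 2 || length(uninduced) < 2)
    stop("need at least two replicates per condition")
  mi <- mean(induced)
  mu <- mean(uninduced)
  fc <- if (mu == 0) Inf else mi / mu
  pooled_var <- stats::var(induced) + stats::var(uninduced)
  # degenerate (zero or numerically-zero) pooled variance: p = 0 when the
  # means differ, 1 when they are equal
  degenerate_p <- function() if (isTRUE(all.equal(mi, mu))) 1 else 0
  if (pooled_var <= 1e-12 * max(mi^2 + mu^2, 1)) {
    p <- degenerate_p()
  } else {
    p <- tryCatch(
      stats::t.test(induced, uninduced, var.equal = TRUE)$p.value,
      error = function(e) degenerate_p())
  }
  direction <- if (fc >= up && p <= alpha) "up"
               else if (fc <= down && p <= alpha) "down"
               else "none"
  list(fc = fc, p = p, direction = direction)
}

#' Consolidate RNA-seq and NanoString direction calls
#'
#' A gene is retained iff the two platforms never contradict each other
#' (opposite nonzero directions) at the shared time points; a nonzero call
#' on one platform against `none` on the other is not a contradiction. The
#' retained profile takes the RNA-seq calls at the RNA-seq time points and
#' the NanoString calls at the NanoString-only time points.
#'
#' @param rnaseq_calls,nano_calls data.frames with columns `gene`, `time`,
#'   `direction`. Genes must be covered by both platforms to be considered.
#' @param rnaseq_times,nano_only_times time points contributed by each
#'   platform (defaults 0/5/9/12 h and 1/3/7 h).
#' @return list with `profile` (data.frame `gene`, `time`, `direction`,
#'   `expressed`, `platform`) and `dropped` (data.frame `gene`, `reason`).
#' @export
integrate_platforms <- function(rnaseq_calls, nano_calls,
                                rnaseq_times = c(0, 5, 9, 12),
                                nano_only_times = c(1, 3, 7)) {
  shared <- intersect(unique(rnaseq_calls$time), unique(nano_calls$time))
  genes <- intersect(unique(rnaseq_calls$gene), unique(nano_calls$gene))
  lookup <- function(calls, g, t) {
    d <- calls$direction[calls$gene == g & calls$time == t]
    if (length(d)) d[1] else "none"
  }
  profile <- list()
  dropped <- list()
  for (g in genes) {
    contradiction <- FALSE
    for (t in shared) {
      r <- lookup(rnaseq_calls, g, t)
      n <- lookup(nano_calls, g, t)
      if (r != "none" && n != "none" && r != n) {
        contradiction <- TRUE
        dropped[[length(dropped) + 1L]] <- data.frame(
          gene = g,
          reason = sprintf("contradiction at %sh: rnaseq=%s nanostring=%s",
                           t, r, n),
          stringsAsFactors = FALSE)
        break
      }
    }
    if (contradiction) next
    rows <- rbind(
      do.call(rbind, lapply(rnaseq_times, function(t) data.frame(
        gene = g, time = t, direction = lookup(rnaseq_calls, g, t),
        platform = "rnaseq", stringsAsFactors = FALSE))),
      do.call(rbind, lapply(nano_only_times, function(t) data.frame(
        gene = g, time = t, direction = lookup(nano_calls, g, t),
        platform = "nanostring", stringsAsFactors = FALSE))))
    profile[[length(profile) + 1L]] <- rows
  }
  profile <- if (length(profile)) do.call(rbind, profile)
             else data.frame(gene = character(), time = numeric(),
                             direction = character(), platform = character(),
                             stringsAsFactors = FALSE)
  profile <- profile[order(profile$gene, profile$time), , drop = FALSE]
  profile$expressed <- profile$direction != "none"
  rownames(profile) <- NULL
  dropped <- if (length(dropped)) do.call(rbind, dropped)
             else data.frame(gene = character(), reason = character(),
                             stringsAsFactors = FALSE)
  list(profile = profile[, c("gene", "time", "direction", "expressed",
                             "platform")],
       dropped = dropped)
}

#' Look up a gene's direction at a time point in an integrated profile
#'
#' @param profile the `profile` component of [integrate_platforms()].
#' @param gene,time scalars.
#' @return `"up"`, `"down"` or `"none"` (also when the gene or time is
#'   absent).
#' @export
profile_direction <- function(profile, gene, time) {
  d <- profile$direction[profile$gene == gene & profile$time == time]
  if (length(d)) d[1] else "none"
}
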