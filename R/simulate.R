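#' Specification for a synthetic RT-qPCR experiment
#'
#' Defines the generative model for Ct data with known ground truth:
#' `Ct(sample, region, well) = base_ct + group_shift + loading(sample) +
#' gene_noise(sample, region) + rt_bias + sample_shift + well_noise`,
#' with loading ~ N(0, loading_sd) per sample, gene noise ~ N(0, noise_sd)
#' per (sample, region) and well noise ~ N(0, replicate_sd).  All noise is
#' additive on the cycle scale, i.e. multiplicative (log-scale) on
#' quantities -- the error structure the stability statistics assume.
#' Dilution series are generated from each region's efficiency via the
#' standard-curve model (slope `-1/log10(1 + E)`, intercept `base_ct`).
#'
#' @param groups named integer vector: samples per group.
#' @param regions data frame with columns `region`, `base_ct` (cycles,
#'   in (10, 40)), `noise_sd` (cycles, >= 0), `efficiency` (fraction in
#'   (0.5, 1.5)).
#' @param group_shifts optional regions x groups matrix of expression
#'   shifts in cycles (default all 0).
#' @param loading_sd SD of the per-sample global loading effect (cycles).
#' @param replicate_sd SD of well-to-well noise (cycles).
#' @param n_replicates wells per (sample, region); default 3.
#' @param rt_bias named vector, group -> extra cycles added to CDS-labelled
#'   regions of that group (models depletion of far-from-poly-A template
#'   under oligo-dT reverse-transcription priming).
#' @param sample_shifts optional regions x samples matrix of per-sample
#'   expression shifts (cycles), e.g. a seasonal profile for a target gene.
#' @param dilution_quantities nominal standard quantities; default the
#'   decade series 100, 10, 1, 0.1, 0.01.
#' @param dilution_replicates wells per dilution point; default 3.
#' @param mask data frame of (`group_id`, `region`) pairs attached to the
#'   emitted table's stability mask.
#' @param rt_primer named vector, group -> reverse-transcription primer.
#' @param max_cycles cycles run; simulated Cts beyond this are emitted as
#'   undetermined.
#' @return Object of class `sim_spec`.
#' @export
sim_spec <- function(groups, regions, group_shifts = NULL, loading_sd = 0.8,
                     replicate_sd = 0.1, n_replicates = 3,
                     rt_bias = NULL, sample_shifts = NULL,
                     dilution_quantities = c(100, 10, 1, 0.1, 0.01),
                     dilution_replicates = 3, mask = NULL, rt_primer = NULL,
                     max_cycles = 40) {
  fail <- function(field, msg) stop("invalid `", field, "`: ", msg, call. = FALSE)
  if (is.null(names(groups)) || any(groups < 1)) fail("groups", "must be a named vector of positive group sizes")
  regions <- as.data.frame(regions)
  need <- c("region", "base_ct", "noise_sd", "efficiency")
  if (!all(need %in% names(regions)))
    fail("regions", paste("needs columns", paste(need, collapse = ", ")))
  if (anyDuplicated(regions$region)) fail("regions", "region names must be unique")
  if (any(regions$base_ct <= 10 | regions$base_ct >= 40))
    fail("base_ct", "must lie in (10, 40)")
  if (any(regions$noise_sd < 0)) fail("noise_sd", "must be >= 0")
  if (any(regions$efficiency <= 0.5 | regions$efficiency >= 1.5))
    fail("efficiency", "must lie in (0.5, 1.5)")
  if (loading_sd < 0) fail("loading_sd", "must be >= 0")
  if (replicate_sd < 0) fail("replicate_sd", "must be >= 0")
  if (any(dilution_quantities <= 0)) fail("dilution_quantities", "must be positive")
  if (is.null(group_shifts)) {
    group_shifts <- matrix(0, nrow(regions), length(groups),
                           dimnames = list(regions$region, names(groups)))
  } else {
    group_shifts <- as.matrix(group_shifts)
    if (!setequal(rownames(group_shifts), regions$region) ||
        !setequal(colnames(group_shifts), names(groups)))
      fail("group_shifts", "dimnames must match regions and groups")
    group_shifts <- group_shifts[regions$region, names(groups), drop = FALSE]
  }
  if (!is.null(rt_bias)) {
    bad <- setdiff(names(rt_bias), names(groups))
    if (length(bad)) fail("rt_bias", paste("unknown group(s):", paste(bad, collapse = ", ")))
  }
  structure(list(groups = groups, regions = regions, group_shifts = group_shifts,
                 loading_sd = loading_sd, replicate_sd = replicate_sd,
                 n_replicates = as.integer(n_replicates), rt_bias = rt_bias,
                 sample_shifts = sample_shifts,
                 dilution_quantities = dilution_quantities,
                 dilution_replicates = as.integer(dilution_replicates),
                 mask = mask, rt_primer = rt_primer, max_cycles = max_cycles),
            class = "sim_spec")
}

#' @export
print.sim_spec <- function(x, ...) {
  cat(sprintf("<sim_spec> %d samples (%s) x %d regions, %d wells/cell\n",
              sum(x$groups),
              paste(sprintf("%s:%d", names(x$groups), x$groups), collapse = ", "),
              nrow(x$regions), x$n_replicates))
  cat(sprintf("  loading_sd %.2f, replicate_sd %.2f, dilution %s\n",
              x$loading_sd, x$replicate_sd,
              paste(x$dilution_quantities, collapse = "/")))
  invisible(x)
}

#' Simulate a complete RT-qPCR experiment
#'
#' Draws a well-level Ct table, per-region dilution series and the latent
#' ground truth from a [sim_spec()].  Deterministic given `seed`.
#'
#' @param spec a [sim_spec()].
#' @param seed integer RNG seed.
#' @return list of class `qpcr_sim` with `ct` (a [ct_table()]),
#'   `dilutions` (long data frame: region, quantity, replicate, ct) and
#'   `truth` (loading effects, per-region noise SDs, efficiencies, group
#'   shifts, and the noise-SD stability order).
#' @export
simulate_qpcr <- function(spec, seed = 1) {
  stopifnot(inherits(spec, "sim_spec"))
  set.seed(seed)
  groups <- rep(names(spec$groups), spec$groups)
  samples <- unlist(lapply(names(spec$groups), function(g)
    sprintf("%s_%d", g, seq_len(spec$groups[[g]]))))
  ns <- length(samples)
  reg <- spec$regions
  nr <- nrow(reg)
  loading <- stats::rnorm(ns, 0, spec$loading_sd)
  names(loading) <- samples

  base <- matrix(reg$base_ct, ns, nr, byrow = TRUE,
                 dimnames = list(samples, reg$region))
  shift <- t(spec$group_shifts[, groups, drop = FALSE])
  rownames(shift) <- samples
  noise <- matrix(stats::rnorm(ns * nr, 0,
                               rep(reg$noise_sd, each = ns)), ns, nr)
  ct0 <- base + shift + loading + noise
  if (!is.null(spec$rt_bias)) {
    cds <- is_cds_region(reg$region)
    for (g in names(spec$rt_bias))
      ct0[groups == g, cds] <- ct0[groups == g, cds] + spec$rt_bias[[g]]
  }
  if (!is.null(spec$sample_shifts)) {
    ss <- spec$sample_shifts
    ct0[colnames(ss), rownames(ss)] <-
      ct0[colnames(ss), rownames(ss)] + t(ss)
  }

  nrep <- spec$n_replicates
  wells <- data.frame(
    sample_id = rep(rep(samples, times = nr), each = nrep),
    group_id = rep(rep(groups, times = nr), each = nrep),
    region = rep(reg$region, each = ns * nrep),
    replicate = rep(seq_len(nrep), times = ns * nr),
    stringsAsFactors = FALSE)
  mu <- rep(as.vector(ct0), each = nrep)
  ct <- mu + stats::rnorm(length(mu), 0, spec$replicate_sd)
  ct[ct > spec$max_cycles] <- NA_real_
  wells$ct <- ct
  if (!is.null(spec$rt_primer))
    wells$rt_primer <- unname(spec$rt_primer[wells$group_id])

  dq <- spec$dilution_quantities
  drep <- spec$dilution_replicates
  dil <- do.call(rbind, lapply(seq_len(nr), function(i) {
    slope <- -1 / log10(1 + reg$efficiency[i])
    mu <- reg$base_ct[i] + slope * log10(dq)
    data.frame(region = reg$region[i],
               quantity = rep(dq, each = drep),
               replicate = rep(seq_len(drep), times = length(dq)),
               ct = rep(mu, each = drep) +
                 stats::rnorm(length(dq) * drep, 0, spec$replicate_sd),
               stringsAsFactors = FALSE)
  }))

  tbl <- ct_table(wells, mask = spec$mask, max_cycles = spec$max_cycles)
  truth <- list(loading = loading,
                noise_sd = stats::setNames(reg$noise_sd, reg$region),
                efficiency = stats::setNames(reg$efficiency, reg$region),
                group_shifts = spec$group_shifts,
                rt_bias = spec$rt_bias,
                stability_order = reg$region[order(reg$noise_sd, reg$region)])
  structure(list(ct = tbl, dilutions = dil, truth = truth, seed = seed),
            class = "qpcr_sim")
}

#' Study-like simulation preset
#'
#' A ready-made [sim_spec()] emulating a reference-gene validation study
#' in a fruit-tree crop: 16 samples in four tissue groups (flower bud FB,
#' n = 4; flower organs FO, n = 6; fruit flesh FF, n = 4; fruit skin FS,
#' n = 2) assayed over 17 candidate amplicon regions of eight genes, with
#' base Cts spanning roughly 21-29 cycles, amplification efficiencies
#' spread over 0.91-1.12, a per-sample loading effect, and a +1 cycle
#' reverse-transcription bias on CDS amplicons in the oligo-dT-primed FB
#' group (depressing the apparent CDS template about two-fold).  The FB x
#' CDS cells are pre-masked for stability ranking, matching how such a
#' priming artefact must be excluded.  Gene-specific noise SDs encode a
#' known stability ordering with `HIS_cds`, `SAND_utr` and `TIP_utr` most
#' stable and `bTUB_utr2`, `ACT_utr2`, `bTUB_utr3` least stable.
#'
#' @param include_targets also simulate two cold-inducible target genes
#'   (`CBF2_utr`, `CBF4_utr`) with a seasonal expression peak in the third
#'   flower-bud sample (mid-winter) and near-absent expression in fruit.
#' @return A [sim_spec()].
#' @export
preset_study_like <- function(include_targets = FALSE) {
  groups <- c(FB = 4L, FO = 6L, FF = 4L, FS = 2L)
  regions <- data.frame(
    region = c("bTUB_utr1", "bTUB_utr2", "bTUB_utr3",
               "HIS_cds", "HIS_utr1", "HIS_utr2",
               "EF1a_cds", "EF1a_utr1", "EF1a_utr2",
               "ANX_cds", "ANX_utr",
               "GAP_utr1", "GAP_utr2",
               "ACT_utr1", "ACT_utr2",
               "SAND_utr", "TIP_utr"),
    base_ct = c(23, 29, 27,
                21, 21.3, 24,
                21.5, 21.6, 22.5,
                23.5, 23,
                24, 22,
                22, 23.5,
                25, 26),
    noise_sd = c(0.30, 0.55, 0.45,
                 0.10, 0.15, 0.35,
                 0.18, 0.18, 0.15,
                 0.35, 0.30,
                 0.25, 0.20,
                 0.25, 0.50,
                 0.10, 0.10),
    efficiency = seq(0.91, 1.12, length.out = 17),
    stringsAsFactors = FALSE)
  gs <- matrix(0, nrow(regions), length(groups),
               dimnames = list(regions$region, names(groups)))
  # group-dependent expression for the least stable regions (about one
  # cycle of spread, matching the strongly group-divergent rankings such
  # regions show in real validation studies)
  gs["bTUB_utr2", ] <- c(1.2, -0.8, 0.6, -1.0)
  gs["bTUB_utr3", ] <- c(-0.8, 1.0, -0.6, 0.4)
  gs["ACT_utr2", ]  <- c(0.8, -0.6, 1.0, -1.2)
  sample_shifts <- NULL
  if (include_targets) {
    regions <- rbind(regions, data.frame(
      region = c("CBF2_utr", "CBF4_utr"),
      base_ct = c(28, 31),
      noise_sd = c(0.2, 0.2),
      efficiency = c(1.0, 1.05)))
    gs <- rbind(gs, CBF2_utr = c(0, 1, 6, 6), CBF4_utr = c(0, 1, 6, 6))
    samples <- unlist(lapply(names(groups), function(g)
      sprintf("%s_%d", g, seq_len(groups[[g]]))))
    # seasonal profile: autumn, late autumn, mid-winter peak, late winter
    season <- c(FB_1 = 2, FB_2 = 0, FB_3 = -3, FB_4 = 1)
    organ <- stats::setNames(c(-1, 0.5, 1, -0.5, 0, 0.8), sprintf("FO_%d", 1:6))
    sample_shifts <- matrix(0, 2, length(samples),
                            dimnames = list(c("CBF2_utr", "CBF4_utr"), samples))
    sample_shifts[, names(season)] <- rep(season, each = 2)
    sample_shifts[, names(organ)] <- rep(organ, each = 2)
  }
  sim_spec(groups = groups, regions = regions, group_shifts = gs,
           loading_sd = 0.8, replicate_sd = 0.1, n_replicates = 3,
           rt_bias = c(FB = 1),
           sample_shifts = sample_shifts,
           mask = data.frame(group_id = "FB",
                             region = c("HIS_cds", "EF1a_cds", "ANX_cds")),
           rt_primer = c(FB = "oligo_dT", FO = "random_hexamer",
                         FF = "random_hexamer", FS = "random_hexamer"))
}
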