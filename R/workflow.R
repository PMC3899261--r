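#' Configuration for the screening pipeline
#'
#' @param nf_size number of reference genes in the normalization factor
#'   (default 3).
#' @param v_cutoff `V_n/n+1` sufficiency cutoff (default 0.15).
#' @param keep regions retained by the delta-Ct first stage (default 6);
#'   `Inf` (or any value >= number of candidates) bypasses stage 1.
#' @param prefilter keep one region per gene symbol before screening (see
#'   [select_representative_regions()]).
#' @param mask data frame of (`group_id`, `region`) pairs masked from
#'   stability ranking, in addition to any mask already on the table.
#' @param candidates optional candidate region subset (default: all
#'   regions present).
#' @param methods stability methods run in stage 3.
#' @return Object of class `study_config`.
#' @export
study_config <- function(nf_size = 3, v_cutoff = 0.15, keep = 6,
                         prefilter = FALSE, mask = NULL, candidates = NULL,
                         methods = c("genorm", "normfinder")) {
  if (nf_size < 2) stop("nf_size must be >= 2", call. = FALSE)
  if (v_cutoff <= 0) stop("v_cutoff must be > 0", call. = FALSE)
  structure(list(nf_size = nf_size, v_cutoff = v_cutoff, keep = keep,
                 prefilter = prefilter, mask = mask, candidates = candidates,
                 methods = match.arg(methods, several.ok = TRUE)),
            class = "study_config")
}

#' Run the end-to-end reference-gene screening pipeline
#'
#' Stage 1 screens all candidates by the delta-Ct statistic (no standard
#' curves needed) and keeps the most stable `keep`; stage 2 fits standard
#' curves from the dilution series and converts the kept regions' Cts to
#' relative quantities; stage 3 ranks them by geNorm (overall and per
#' group) and NormFinder (multi-group overall, single-group per group);
#' stage 4 builds the geometric-mean normalization factor from the geNorm
#' trio and checks `V_3/4` against the cutoff.
#'
#' @param table a well-level or collapsed [ct_table()].
#' @param dilutions dilution-series data frame (region, quantity, ct), as
#'   from [simulate_qpcr()] or [read_dilution_series()].
#' @param config a [study_config()].
#' @return Object of class `refgene_report`.
#' @export
run_screening_pipeline <- function(table, dilutions, config = study_config()) {
  stopifnot(inherits(table, "ct_table"), inherits(config, "study_config"))
  if (!is.null(config$mask)) table <- apply_mask(table, config$mask)
  if (!table$collapsed) table <- collapse_replicates(table)
  m <- ct_matrix(table)
  candidates <- config$candidates
  if (is.null(candidates)) candidates <- colnames(m)

  # stage 1: delta-Ct screen
  stage1 <- tryCatch({
    mm <- m[, candidates, drop = FALSE]
    attr(mm, "mask") <- attr(m, "mask")[, candidates, drop = FALSE]
    if (config$prefilter) {
      keep_r <- select_representative_regions(mm)
      mm <- mm[, keep_r, drop = FALSE]
    }
    full <- delta_ct_rank(mm)
    k <- min(config$keep, length(full$ranking))
    if (k < 3) stop("keep must allow at least 3 regions", call. = FALSE)
    list(result = full, kept = full$ranking[seq_len(k)])
  }, error = function(e) stop("stage 1 (delta-Ct screen): ",
                              conditionMessage(e), call. = FALSE))
  kept <- stage1$kept

  # stage 2: standard curves + quantification
  stage2 <- tryCatch({
    dil <- dilutions[dilutions$region %in% kept, , drop = FALSE]
    curves <- fit_standard_curves(dil)
    missing_c <- setdiff(kept, names(curves))
    if (length(missing_c))
      stop("no dilution series for region(s): ",
           paste(missing_c, collapse = ", "), call. = FALSE)
    msub <- m[, kept, drop = FALSE]
    attr(msub, "mask") <- attr(m, "mask")[, kept, drop = FALSE]
    attr(msub, "groups") <- attr(m, "groups")
    list(curves = curves, q = quantify(msub, curves))
  }, error = function(e) stop("stage 2 (quantification): ",
                              conditionMessage(e), call. = FALSE))
  q <- stage2$q
  groups <- attr(q, "groups")

  # stage 3: stability rankings, overall and per group
  stage3 <- tryCatch({
    out <- list()
    if ("genorm" %in% config$methods) {
      out$genorm <- list(overall = genorm(q, cutoff = config$v_cutoff))
      out$genorm$per_group <- per_group_apply(q, groups, function(qs)
        genorm(qs, cutoff = config$v_cutoff))
    }
    if ("normfinder" %in% config$methods) {
      out$normfinder <- list(overall = normfinder(q, groups, mode = "multi_group"))
      out$normfinder$per_group <- per_group_apply(q, groups, function(qs)
        normfinder(qs, mode = "single_group"))
    }
    out
  }, error = function(e) stop("stage 3 (stability ranking): ",
                              conditionMessage(e), call. = FALSE))

  # stage 4: normalization factor and sufficiency verdict
  stage4 <- tryCatch({
    ranking <- if (!is.null(stage3$genorm)) stage3$genorm$overall$ranking
               else stage3$normfinder$overall$ranking
    refs <- ranking[seq_len(config$nf_size)]
    nf <- normalization_factor(q, refs)
    v34 <- if (!is.null(stage3$genorm))
      stage3$genorm$overall$v_curve$v[stage3$genorm$overall$v_curve$n == config$nf_size]
    else v_pairwise_nf(q, ranking, config$v_cutoff)$v_curve$v[config$nf_size - 1]
    verdict <- if (length(v34) && !is.na(v34) && v34 < config$v_cutoff)
      sprintf("%d genes sufficient", config$nf_size)
    else sprintf("more than %d genes recommended", config$nf_size)
    list(references = refs, nf = nf, v = if (length(v34)) v34 else NA_real_,
         verdict = verdict, cv = cv_of_normalized(q, refs))
  }, error = function(e) stop("stage 4 (normalization factor): ",
                              conditionMessage(e), call. = FALSE))

  structure(list(config = config, screening = stage1, curves = stage2$curves,
                 quantities = q, rankings = stage3, selection = stage4),
            class = "refgene_report")
}

per_group_apply <- function(q, groups, f) {
  out <- list()
  for (g in unique(groups)) {
    idx <- which(groups == g)
    if (length(idx) < 2) next
    qs <- q[idx, , drop = FALSE]
    attr(qs, "mask") <- attr(q, "mask")[idx, , drop = FALSE]
    keep <- colSums(is.finite(qs) & !attr(qs, "mask")) >= 2
    qq <- qs[, keep, drop = FALSE]
    attr(qq, "mask") <- attr(qs, "mask")[, keep, drop = FALSE]
    out[[g]] <- tryCatch(f(qq), error = function(e) NULL)
  }
  out
}

#' @export
print.refgene_report <- function(x, ...) {
  cat("<refgene_report>\n")
  cat("  stage 1 kept:", paste(x$screening$kept, collapse = ", "), "\n")
  if (!is.null(x$rankings$genorm)) {
    g <- x$rankings$genorm$overall
    cat("  geNorm trio:", paste(g$final_trio, collapse = ", "),
        sprintf("(trio M = %.3f)\n", g$trio_m))
  }
  if (!is.null(x$rankings$normfinder)) {
    n <- x$rankings$normfinder$overall
    cat(sprintf("  NormFinder best: %s (%.3f); best pair: %s (%.3f)\n",
                n$best_region, n$stability[n$best_region],
                paste(n$best_pair$pair, collapse = " + "), n$best_pair$stability))
  }
  cat(sprintf("  NF references: %s | V = %.3f -> %s\n",
              paste(x$selection$references, collapse = ", "),
              x$selection$v, x$selection$verdict))
  cat(sprintf("  mean CV of normalized references: %.3f\n", x$selection$cv$mean_cv))
  invisible(x)
}

#' Normalize a target gene by a reference set
#'
#' `normalized(sample) = q_target / NF_n(sample)`; per-sample loading
#' effects common to target and references cancel.
#'
#' @param q quantity matrix containing target and reference regions.
#' @param target_region the target gene region.
#' @param reference_set reference regions (>= 2, not containing target).
#' @param groups optional sample-to-group map for group means.
#' @return Object of class `normalized_expression` with `values`
#'   (per-sample) and `group_means`.
#' @export
normalize_target <- function(q, target_region, reference_set, groups = NULL) {
  q <- as_quantity_matrix(q)
  if (target_region %in% reference_set)
    stop("configuration error: target must not be in the reference set",
         call. = FALSE)
  if (!target_region %in% colnames(q))
    stop("unknown target region '", target_region, "'", call. = FALSE)
  nf <- normalization_factor(q, reference_set)
  vals <- q[, target_region] / nf
  groups <- resolve_groups(q, groups)
  gm <- NULL
  if (!is.null(groups))
    gm <- tapply(vals, groups, function(x) mean(x[is.finite(x)]))
  structure(list(target_region = target_region, reference_set = reference_set,
                 values = vals, nf = nf, group_means = gm),
            class = "normalized_expression")
}

#' @export
print.normalized_expression <- function(x, ...) {
  cat(sprintf("<normalized_expression> %s / NF_%d(%s)\n", x$target_region,
              length(x$reference_set), paste(x$reference_set, collapse = ", ")))
  print(round(x$values, 4))
  invisible(x)
}

#' Compare normalization by two reference sets
#'
#' Normalizes the target by a "best" and a "worst" reference set and
#' reports the per-sample ratio of the two normalized profiles, its fold
#' range and median, and the correlation of the within-group-centred log2
#' profiles (groups with >= 2 samples, pooled after centring) -- the
#' robustness check of whether an inferior reference set shifts the scale
#' without distorting relative expression within groups.
#'
#' @inheritParams normalize_target
#' @param best_set,worst_set reference sets (size >= 2, neither containing
#'   the target; the two sets may overlap each other).
#' @return Object of class `ref_comparison`: `ratio` (worst/best per
#'   sample), `median_fold`, `fold_range`, `log_correlation`.
#' @export
robustness_compare <- function(q, target_region, best_set, worst_set,
                               groups = NULL) {
  if (length(best_set) < 2 || length(worst_set) < 2)
    stop("reference sets must contain at least 2 regions", call. = FALSE)
  if (target_region %in% c(best_set, worst_set))
    stop("configuration error: target overlaps a reference set", call. = FALSE)
  nb <- normalize_target(q, target_region, best_set, groups)
  nw <- normalize_target(q, target_region, worst_set, groups)
  ratio <- nw$values / nb$values
  ok <- is.finite(ratio)
  groups <- resolve_groups(as_quantity_matrix(q), groups)
  centred <- function(v) {
    lv <- log2(v)
    if (is.null(groups)) return(lv - mean(lv, na.rm = TRUE))
    unsplit(lapply(split(lv, groups), function(x) x - mean(x, na.rm = TRUE)),
            groups)
  }
  cb <- centred(nb$values)
  cw <- centred(nw$values)
  use <- is.finite(cb) & is.finite(cw)
  if (!is.null(groups)) {
    big <- names(which(table(groups[use]) >= 2))
    use <- use & groups %in% big
  }
  corr <- if (sum(use) >= 3) stats::cor(cb[use], cw[use]) else NA_real_
  structure(list(target_region = target_region, best_set = best_set,
                 worst_set = worst_set, ratio = ratio,
                 median_fold = stats::median(ratio[ok]),
                 fold_range = range(ratio[ok]),
                 log_correlation = corr,
                 normalized_best = nb$values, normalized_worst = nw$values),
            class = "ref_comparison")
}

#' @export
print.ref_comparison <- function(x, ...) {
  cat(sprintf("<ref_comparison> %s: worst/best median fold %.2f (range %.2f-%.2f)\n",
              x$target_region, x$median_fold, x$fold_range[1], x$fold_range[2]))
  cat(sprintf("  within-group log2 profile correlation: %.3f\n",
              x$log_correlation))
  invisible(x)
}

#' Coefficient of variation of normalized reference quantities
#'
#' For each region of the reference set, the quantity is divided by the
#' set's own normalization factor and the CV (SD/mean over samples) of
#' that normalized series reported: a direct measure of residual
#' post-normalization variation of the chosen references.
#'
#' @inheritParams normalize_target
#' @param reference_set reference regions (>= 2).
#' @return list with `per_region` CVs and their `mean_cv`.
#' @export
cv_of_normalized <- function(q, reference_set) {
  q <- as_quantity_matrix(q)
  if (length(reference_set) < 2)
    stop("reference set must contain at least 2 regions", call. = FALSE)
  nf <- normalization_factor(q, reference_set)
  cvs <- vapply(reference_set, function(r) {
    x <- q[, r] / nf
    x <- x[is.finite(x)]
    stats::sd(x) / mean(x)
  }, numeric(1))
  list(per_region = cvs, mean_cv = mean(cvs))
}

#' Write a machine- and human-readable run report
#'
#' Emits `report.json`, `report.md`, and CSV tables (geNorm ranking,
#' V-curve, delta-Ct ranking, NormFinder stabilities, per-sample NF) into
#' `dir`.  Output is deterministic: identical inputs give byte-identical
#' files (no timestamps).
#'
#' @param report a [run_screening_pipeline()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "refgene_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  version <- as.character(utils::packageVersion("refstab"))
  hdr <- sprintf("# refstab %s", version)
  wcsv <- function(df, file) {
    path <- file.path(dir, file)
    writeLines(hdr, path)
    suppressWarnings(utils::write.table(df, path, sep = ",", row.names = FALSE,
                                        col.names = TRUE, append = TRUE,
                                        quote = FALSE))
    path
  }
  dct <- summary(report$screening$result)
  wcsv(dct, "deltact_ranking.csv")
  json <- list(version = version,
               kept = report$screening$kept,
               deltact = list(mean_sd = as.list(report$screening$result$mean_sd)),
               references = report$selection$references,
               v = report$selection$v,
               verdict = report$selection$verdict,
               cv = list(per_region = as.list(report$selection$cv$per_region),
                         mean = report$selection$cv$mean_cv),
               nf = as.list(round(report$selection$nf, 10)))
  md <- c("# Reference-gene screening report", "",
          paste0("Stage 1 kept: ", paste(report$screening$kept, collapse = ", ")), "")
  if (!is.null(report$rankings$genorm)) {
    g <- report$rankings$genorm$overall
    wcsv(summary(g)$ranking, "genorm_ranking.csv")
    wcsv(g$v_curve, "genorm_v_curve.csv")
    json$genorm <- list(ranking = g$ranking, m_values = as.list(g$m_values),
                        final_trio = g$final_trio, trio_m = g$trio_m,
                        v_curve = g$v_curve, sufficient_n = g$sufficient_n)
    md <- c(md, sprintf("geNorm trio: %s (trio M = %.3f); sufficient n = %s",
                        paste(g$final_trio, collapse = ", "), g$trio_m,
                        ifelse(is.na(g$sufficient_n), "not reached", g$sufficient_n)), "")
  }
  if (!is.null(report$rankings$normfinder)) {
    n <- report$rankings$normfinder$overall
    wcsv(summary(n), "normfinder_ranking.csv")
    json$normfinder <- list(stability = as.list(n$stability),
                            best_region = n$best_region,
                            best_pair = n$best_pair)
    md <- c(md, sprintf("NormFinder best: %s (%.3f); best pair %s (%.3f)",
                        n$best_region, n$stability[n$best_region],
                        paste(n$best_pair$pair, collapse = " + "),
                        n$best_pair$stability), "")
  }
  md <- c(md, sprintf("Normalization: %s; V = %.3f -> %s; mean CV = %.3f",
                      paste(report$selection$references, collapse = ", "),
                      report$selection$v, report$selection$verdict,
                      report$selection$cv$mean_cv))
  jsonlite::write_json(json, file.path(dir, "report.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  writeLines(md, file.path(dir, "report.md"))
  invisible(dir)
}
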