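#' Fit a dilution-series standard curve
#'
#' Ordinary least squares of Ct on log10(nominal quantity) over a dilution
#' series (the conventional design is five decade steps, relative
#' quantities 100, 10, 1, 0.1, 0.01).  The amplification efficiency is
#' derived from the slope as `E = 10^(-1/slope) - 1`, so a perfect
#' per-cycle doubling gives slope -3.3219 and E = 1 (100%).
#'
#' @param series data frame with columns `quantity` and `ct` (replicate
#'   wells may be given as repeated quantities; they enter the regression
#'   individually and are averaged for the reported dilution points).
#' @param region optional region name attached to the result.
#' @return Object of class `standard_curve` with elements `slope`,
#'   `intercept` (Ct at quantity 1), `efficiency`, `r_squared`,
#'   `dilution_points`.
#' @examples
#' s <- data.frame(quantity = 10^(2:-2), ct = 20 + (0:4) / log10(2))
#' fit_standard_curve(s)
#' @export
fit_standard_curve <- function(series, region = NULL) {
  series <- as.data.frame(series)
  if (!all(c("quantity", "ct") %in% names(series)))
    stop("series needs columns quantity, ct", call. = FALSE)
  series <- series[is.finite(series$quantity) & is.finite(series$ct), ]
  if (any(series$quantity <= 0))
    stop("nominal quantities must be strictly positive", call. = FALSE)
  if (length(unique(series$quantity)) < 3)
    stop("insufficient data: at least 3 distinct dilution points required",
         call. = FALSE)
  fit <- stats::lm(ct ~ log10(quantity), data = series)
  slope <- unname(stats::coef(fit)[2])
  if (!is.finite(slope) || slope >= 0)
    stop("invalid curve: fitted slope must be negative (Ct decreasing with quantity)",
         call. = FALSE)
  pts <- aggregate(ct ~ quantity, data = series, FUN = mean)
  pts <- pts[order(-pts$quantity), ]
  sst <- sum((series$ct - mean(series$ct))^2)
  r2 <- if (sst > 0) 1 - sum(stats::resid(fit)^2) / sst else 1
  structure(list(region = region, slope = slope,
                 intercept = unname(stats::coef(fit)[1]),
                 efficiency = slope_to_efficiency(slope),
                 r_squared = r2,
                 dilution_points = pts),
            class = "standard_curve")
}

#' @rdname fit_standard_curve
#' @param slope standard-curve slope in cycles per log10(quantity).
#' @export
slope_to_efficiency <- function(slope) 10^(-1 / slope) - 1

#' Fit standard curves for every region of a dilution table
#'
#' @param dilutions data frame as returned by [read_dilution_series()] or
#'   emitted by [simulate_qpcr()]: columns `region`, `quantity`, `ct`.
#' @return Named list of [fit_standard_curve()] results.
#' @export
fit_standard_curves <- function(dilutions) {
  dilutions <- as.data.frame(dilutions)
  out <- lapply(split(dilutions, dilutions$region), function(d)
    fit_standard_curve(d, region = d$region[1]))
  out[order(names(out))]
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf("<standard_curve>%s slope %.4f, intercept %.3f, E = %.1f%%, r2 = %.4f (%d points)\n",
              if (is.null(x$region)) "" else paste0(" ", x$region),
              x$slope, x$intercept, 100 * x$efficiency, x$r_squared,
              nrow(x$dilution_points)))
  invisible(x)
}

#' Convert Cts to relative quantities via standard curves
#'
#' Inverts each region's curve: `quantity = 10^((Ct - intercept) / slope)`.
#' Regions lacking a curve fall back to an assumed efficiency, for which
#' quantities are expressed relative to the region's mean Ct,
#' `q = (1 + E)^(mean(Ct) - Ct)`.  Undetermined cells become missing;
#' the stability mask propagates.
#'
#' @param table a [ct_table()] (collapsed, or collapsed on the fly) or a
#'   Ct matrix from [ct_matrix()].
#' @param curves named list of [fit_standard_curve()] objects.
#' @param efficiencies optional named fallback efficiencies (fractions,
#'   1 = 100%) for regions without a curve.
#' @return samples x regions quantity matrix with `groups`, `mask` and
#'   `provenance` attributes.
#' @export
quantify <- function(table, curves = NULL, efficiencies = NULL) {
  m <- if (inherits(table, "ct_table")) ct_matrix(table) else table
  q <- m
  prov <- character(ncol(m))
  names(prov) <- colnames(m)
  for (r in colnames(m)) {
    cv <- curves[[r]]
    if (!is.null(cv)) {
      q[, r] <- 10^((m[, r] - cv$intercept) / cv$slope)
      prov[r] <- "standard_curve"
    } else if (!is.null(efficiencies) && !is.na(efficiencies[r])) {
      e <- efficiencies[[r]]
      q[, r] <- (1 + e)^(mean(m[, r], na.rm = TRUE) - m[, r])
      prov[r] <- "assumed_efficiency"
    } else {
      stop("no standard curve or fallback efficiency for region '", r, "'",
           call. = FALSE)
    }
  }
  attr(q, "groups") <- attr(m, "groups")
  attr(q, "mask") <- attr(m, "mask")
  attr(q, "provenance") <- prov
  q
}

#' Ratio of initial template amounts between two amplicon regions
#'
#' For amplicons of the same gene read at a common fluorescence threshold
#' `T` (baseline-subtracted Rn, conventionally 0.3), the initial template
#' amount is `Q0 = T / (1 + E)^Ct`, so the CDS : 3'-UTR ratio per sample is
#' `Q0_cds / Q0_utr`.  The threshold cancels when shared, but is carried
#' explicitly.  Ratios below 1 indicate depleted long-distance (CDS)
#' template, the signature of oligo-dT-primed reverse transcription read
#' far from the poly-A tail.
#'
#' @param table a [ct_table()] or Ct matrix.
#' @param cds_region,utr_region region names to compare.
#' @param efficiencies named amplification efficiencies (fractions in
#'   (0.5, 1.5)) for the two regions.
#' @param threshold_rn fluorescence threshold `T`; default 0.3.
#' @return Object of class `template_ratio`: per-sample ratios and a
#'   per-group (mean, sd, n) summary.
#' @export
template_ratio <- function(table, cds_region, utr_region, efficiencies,
                           threshold_rn = 0.3) {
  m <- if (inherits(table, "ct_table")) ct_matrix(table) else table
  for (r in c(cds_region, utr_region))
    if (!r %in% colnames(m)) stop("unknown region '", r, "'", call. = FALSE)
  e <- efficiencies[c(cds_region, utr_region)]
  if (anyNA(e)) stop("efficiencies required for both regions", call. = FALSE)
  if (any(e <= 0.5 | e >= 1.5))
    stop("efficiencies must lie in (0.5, 1.5)", call. = FALSE)
  shared <- is.finite(m[, cds_region]) & is.finite(m[, utr_region])
  if (sum(shared) < 1)
    stop("insufficient data: no shared samples with finite Ct", call. = FALSE)
  q0 <- function(ct, eff) threshold_rn / (1 + eff)^ct
  ratio <- ifelse(shared,
                  q0(m[, cds_region], e[[cds_region]]) /
                    q0(m[, utr_region], e[[utr_region]]),
                  NA_real_)
  names(ratio) <- rownames(m)
  groups <- attr(m, "groups")
  summ <- NULL
  if (!is.null(groups)) {
    summ <- do.call(rbind, lapply(split(ratio, groups), function(x) {
      x <- x[is.finite(x)]
      data.frame(mean = mean(x), sd = if (length(x) > 1) stats::sd(x) else NA_real_,
                 n = length(x))
    }))
    summ <- data.frame(group = rownames(summ), summ, row.names = NULL)
  }
  structure(list(gene = region_gene(cds_region), cds_region = cds_region,
                 utr_region = utr_region, threshold_rn = threshold_rn,
                 efficiencies = e, per_sample_ratio = ratio,
                 group_summary = summ),
            class = "template_ratio")
}

#' @export
print.template_ratio <- function(x, ...) {
  cat(sprintf("<template_ratio> %s / %s (Rn threshold %.2f)\n",
              x$cds_region, x$utr_region, x$threshold_rn))
  all_r <- x$per_sample_ratio[is.finite(x$per_sample_ratio)]
  cat(sprintf("  overall: %.3f +/- %.3f (n = %d)\n", mean(all_r),
              stats::sd(all_r), length(all_r)))
  if (!is.null(x$group_summary)) {
    s <- x$group_summary
    for (i in seq_len(nrow(s)))
      cat(sprintf("  %s: %.3f +/- %.3f (n = %d)\n", s$group[i], s$mean[i],
                  s$sd[i], s$n[i]))
  }
  invisible(x)
}
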