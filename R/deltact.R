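#' Delta-Ct stability screen
#'
#' Ranks candidate reference regions directly on Ct values, with no
#' standard curve: for each pair of regions the per-sample Ct difference
#' is formed and its sample standard deviation (n - 1 denominator) taken;
#' a region's score is the mean SD over all its partners, and regions are
#' ranked ascending (ties broken lexicographically).  Per-sample global
#' shifts (template loading) cancel in the differences.
#'
#' @param table a [ct_table()] (collapsed on the fly if needed) or a
#'   samples x regions Ct matrix from [ct_matrix()].
#' @param regions optional candidate subset (default: all regions).
#' @param min_shared minimum shared finite samples per pair; pairs below
#'   this are omitted and flagged, regions with no valid pair dropped with
#'   a warning.
#' @return Object of class `delta_ct`: `pair_sd` (symmetric matrix,
#'   cycles), `mean_sd`, `ranking`, `dropped_pairs`.
#' @export
delta_ct_rank <- function(table, regions = NULL, min_shared = 2L) {
  m <- if (inherits(table, "ct_table")) ct_matrix(table) else table
  mask <- attr(m, "mask")
  if (!is.null(mask)) m[mask] <- NA_real_
  if (!is.null(regions)) {
    unknown <- setdiff(regions, colnames(m))
    if (length(unknown))
      stop("unknown region(s): ", paste(unknown, collapse = ", "), call. = FALSE)
    m <- m[, regions, drop = FALSE]
  }
  R <- ncol(m)
  if (R < 2) stop("at least 2 regions required", call. = FALSE)
  nm <- colnames(m)
  ps <- matrix(NA_real_, R, R, dimnames = list(nm, nm))
  diag(ps) <- 0
  dropped <- character(0)
  for (j in seq_len(R - 1L)) {
    for (k in (j + 1L):R) {
      d <- m[, j] - m[, k]
      d <- d[is.finite(d)]
      if (length(d) < min_shared) {
        dropped <- c(dropped, paste(nm[j], nm[k], sep = ":"))
      } else {
        ps[j, k] <- ps[k, j] <- stats::sd(d)
      }
    }
  }
  mean_sd <- vapply(seq_len(R), function(j) {
    v <- ps[j, -j]
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  }, numeric(1))
  names(mean_sd) <- nm
  if (anyNA(mean_sd)) {
    warning("dropping region(s) with no valid pair: ",
            paste(nm[is.na(mean_sd)], collapse = ", "), call. = FALSE)
    keep <- !is.na(mean_sd)
    ps <- ps[keep, keep, drop = FALSE]
    mean_sd <- mean_sd[keep]
  }
  ord <- order(mean_sd, names(mean_sd))
  structure(list(pair_sd = ps, mean_sd = mean_sd,
                 ranking = names(mean_sd)[ord], dropped_pairs = dropped),
            class = "delta_ct")
}

#' @export
print.delta_ct <- function(x, ...) {
  cat("<delta_ct> ranking by mean SD of pairwise delta-Ct (cycles):\n")
  s <- x$mean_sd[x$ranking]
  for (i in seq_along(s))
    cat(sprintf("  %2d. %-12s %.3f\n", i, names(s)[i], s[i]))
  if (length(x$dropped_pairs))
    cat("  omitted pairs:", paste(x$dropped_pairs, collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.delta_ct <- function(object, ...) {
  data.frame(rank = seq_along(object$ranking), region = object$ranking,
             mean_sd = unname(object$mean_sd[object$ranking]), row.names = NULL)
}

#' @export
plot.delta_ct <- function(x, ...) {
  op <- graphics::par(mar = c(7, 4, 2, 1))
  on.exit(graphics::par(op))
  graphics::barplot(x$mean_sd[x$ranking], las = 2, cex.names = 0.7,
                    ylab = "mean SD of delta-Ct (cycles)",
                    main = "delta-Ct screen", ...)
  invisible(x)
}

#' First-stage screening of reference candidates
#'
#' Runs the delta-Ct screen and keeps the `keep` most stable regions,
#' the recommended cheap first pass over ten or more candidates before the
#' curve-based geNorm / NormFinder evaluation (five or six kept genes is
#' the conventional choice).
#'
#' @inheritParams delta_ct_rank
#' @param keep number of regions to retain (>= 3, <= number of regions).
#' @param prefilter if TRUE, first keep only one region per gene symbol --
#'   the one with the narrowest Ct interquartile range -- so trivially
#'   correlated homologue amplicons do not inflate apparent stability.
#' @return Character vector of selected regions (best first) with the full
#'   [delta_ct_rank()] result attached as attribute `ranking`.
#' @export
screen_candidates <- function(table, regions = NULL, keep = 6, prefilter = FALSE) {
  m <- if (inherits(table, "ct_table")) ct_matrix(table) else table
  if (!is.null(regions)) m <- m[, regions, drop = FALSE]
  if (prefilter) {
    pick <- select_representative_regions(m)
    m <- m[, pick, drop = FALSE]
  }
  if (keep < 3 || keep > ncol(m))
    stop("keep must lie between 3 and the number of candidate regions (",
         ncol(m), ")", call. = FALSE)
  res <- delta_ct_rank(m)
  structure(res$ranking[seq_len(keep)], ranking = res)
}

#' One region per gene with the narrowest Ct distribution
#'
#' @param m samples x regions Ct matrix.
#' @return character vector with one region per gene symbol, chosen by the
#'   smallest interquartile range of Ct.
#' @export
select_representative_regions <- function(m) {
  mask <- attr(m, "mask")
  if (!is.null(mask)) m[mask] <- NA_real_
  genes <- region_gene(colnames(m))
  iqr <- apply(m, 2, stats::IQR, na.rm = TRUE)
  unname(vapply(split(colnames(m), genes), function(rs) {
    rs[order(iqr[rs], rs)][1]
  }, character(1)))
}
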