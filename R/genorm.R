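#' Pairwise variation V between two gene regions
#'
#' The geNorm building block: the sample standard deviation (n - 1
#' denominator) of the log2 expression ratio of two regions, computed over
#' the samples where both are observed and unmasked.  Proportional regions
#' give V = 0; V is symmetric and invariant to per-sample global scaling.
#'
#' @param q samples x regions quantity matrix (see [quantify()]).
#' @param region_j,region_k region names or column indices.
#' @param min_shared minimum shared samples per pair (default 2).
#' @return V, in log2 units.
#' @export
pairwise_variation <- function(q, region_j, region_k, min_shared = 2L) {
  L <- log2_quantities(q)
  d <- L[, region_j] - L[, region_k]
  d <- d[is.finite(d)]
  if (length(d) < min_shared)
    stop("insufficient data: fewer than ", min_shared,
         " shared samples for pair (", region_j, ", ", region_k, ")", call. = FALSE)
  stats::sd(d)
}

# All pairwise V values at once (upper+lower triangle, 0 diagonal).
pair_sd_matrix <- function(L, min_shared = 2L) {
  R <- ncol(L)
  V <- matrix(0, R, R, dimnames = list(colnames(L), colnames(L)))
  for (j in seq_len(R - 1L)) {
    for (k in (j + 1L):R) {
      d <- L[, j] - L[, k]
      d <- d[is.finite(d)]
      if (length(d) < min_shared)
        stop("insufficient data: fewer than ", min_shared,
             " shared samples for pair (", colnames(L)[j], ", ",
             colnames(L)[k], ")", call. = FALSE)
      V[j, k] <- V[k, j] <- stats::sd(d)
    }
  }
  V
}

#' geNorm expression-stability value M
#'
#' `M_j` is the mean pairwise variation of region `j` against every other
#' region of the active set; lower M means more stable expression.
#'
#' @inheritParams pairwise_variation
#' @param region_j the region scored.
#' @param active character vector of active regions (>= 3, containing
#'   `region_j`); defaults to all regions of `q`.
#' @return M, in log2 units.
#' @export
m_value <- function(q, region_j, active = colnames(as_quantity_matrix(q))) {
  if (length(active) < 3)
    stop("M is defined for an active set of at least 3 regions", call. = FALSE)
  if (!region_j %in% active)
    stop("region '", region_j, "' is not in the active set", call. = FALSE)
  L <- log2_quantities(q)[, active, drop = FALSE]
  V <- pair_sd_matrix(L)
  mean(V[region_j, setdiff(active, region_j)])
}

#' geNorm stability ranking with stepwise elimination
#'
#' Computes M for all regions, repeatedly removes the region with the
#' highest M (ties broken by removing the lexicographically last name),
#' and stops when three regions remain.  The retained trio is reported as
#' a set with the per-region M values of the final stage and their mean
#' (`trio_m`, the single number conventionally quoted for the best trio).
#' Also evaluates the normalization-factor pairwise variation `V_n/n+1`
#' along the stability ordering and the smallest sufficient `n` under the
#' cutoff (default 0.15).
#'
#' @inheritParams pairwise_variation
#' @param cutoff `V_n/n+1` threshold below which `n` references are deemed
#'   sufficient; default 0.15.
#' @return Object of class `genorm` with `m_values` (M at elimination, or
#'   final-stage M for the trio), `elimination_order` (least stable first),
#'   `final_trio`, `trio_m`, `ranking` (best first), `v_curve`,
#'   `sufficient_n`, `trace`.
#' @export
genorm <- function(q, cutoff = 0.15, min_shared = 2L) {
  q <- structure(as_quantity_matrix(q), mask = attr(q, "mask"),
                 groups = attr(q, "groups"))
  L <- log2_quantities(q)
  usable <- colSums(is.finite(L)) >= 2
  if (any(!usable)) {
    warning("dropping region(s) with fewer than 2 usable samples: ",
            paste(colnames(L)[!usable], collapse = ", "), call. = FALSE)
    L <- L[, usable, drop = FALSE]
  }
  if (ncol(L) < 4)
    stop("stepwise ranking needs at least 4 usable regions; use m_value() directly",
         call. = FALSE)
  V <- pair_sd_matrix(L, min_shared)
  active <- colnames(L)
  trace <- list()
  m_at_removal <- numeric(0)
  elim <- character(0)
  while (length(active) > 3) {
    M <- vapply(active, function(j) mean(V[j, setdiff(active, j)]), numeric(1))
    worst <- max(M)
    cand <- names(M)[M >= worst - 1e-15]
    drop <- max(sort(cand))  # deterministic tie-break: lexicographically last
    trace[[length(trace) + 1L]] <- list(step = length(trace) + 1L,
                                        active = active, m = M, removed = drop,
                                        tie = length(cand) > 1)
    elim <- c(elim, drop)
    m_at_removal[drop] <- M[[drop]]
    active <- setdiff(active, drop)
  }
  final_m <- vapply(active, function(j) mean(V[j, setdiff(active, j)]), numeric(1))
  m_values <- c(m_at_removal, final_m)
  ranking <- c(names(sort(final_m)), rev(elim))
  lf <- log2_quantities(q)[, ranking, drop = FALSE]
  vres <- v_curve_from_log(lf, cutoff)
  structure(list(m_values = m_values[ranking],
                 elimination_order = elim,
                 final_trio = sort(active),
                 trio_m = mean(final_m),
                 ranking = ranking,
                 v_curve = vres$v_curve,
                 sufficient_n = vres$sufficient_n,
                 cutoff = cutoff,
                 pair_v = V,
                 trace = trace),
            class = "genorm")
}

#' Geometric-mean normalization factor
#'
#' `NF_n(sample) = (prod of the n selected reference quantities)^(1/n)`.
#' A sample with any selected region missing gets a missing NF.
#'
#' @inheritParams pairwise_variation
#' @param regions the selected reference regions (>= 2).
#' @return Named per-sample NF vector.
#' @export
normalization_factor <- function(q, regions) {
  q <- as_quantity_matrix(q)
  if (length(regions) < 2)
    stop("a normalization factor needs at least 2 reference regions", call. = FALSE)
  missing_r <- setdiff(regions, colnames(q))
  if (length(missing_r))
    stop("unknown region(s): ", paste(missing_r, collapse = ", "), call. = FALSE)
  sub <- q[, regions, drop = FALSE]
  apply(sub, 1, geo_mean)
}

# V_n/n+1 from a log2-quantity matrix already ordered best-first.
v_curve_from_log <- function(L, cutoff) {
  R <- ncol(L)
  ns <- 2:(R - 1)
  v <- vapply(ns, function(n) {
    d <- rowMeans(L[, seq_len(n), drop = FALSE]) -
      rowMeans(L[, seq_len(n + 1), drop = FALSE])
    d <- d[is.finite(d)]
    if (length(d) < 2) return(NA_real_)
    stats::sd(d)
  }, numeric(1))
  ok <- which(!is.na(v) & v < cutoff)
  list(v_curve = data.frame(n = ns, v = v),
       sufficient_n = if (length(ok)) ns[min(ok)] else NA_integer_)
}

#' Normalization-factor pairwise variation V_n/n+1
#'
#' For each `n`, compares the normalization factors built from the `n` and
#' `n + 1` most stable regions: `V_n/n+1` is the sample standard deviation
#' of `log2(NF_n / NF_{n+1})`.  A value below the cutoff means adding the
#' (n+1)-th gene no longer changes the factor appreciably, i.e. `n`
#' references suffice.
#'
#' @inheritParams genorm
#' @param ranked_regions regions ordered most stable first (>= 3).
#' @return list with `v_curve` (data frame of `n`, `v`) and `sufficient_n`
#'   (smallest `n` with `V < cutoff`, `NA` when never reached).
#' @export
v_pairwise_nf <- function(q, ranked_regions, cutoff = 0.15) {
  if (length(ranked_regions) < 3)
    stop("need at least 3 ranked regions", call. = FALSE)
  L <- log2_quantities(q)[, ranked_regions, drop = FALSE]
  v_curve_from_log(L, cutoff)
}

#' @export
print.genorm <- function(x, ...) {
  cat("<genorm> stability ranking (best first)\n")
  cat("  final trio:", paste(x$final_trio, collapse = ", "),
      sprintf("(trio M = %.3f)\n", x$trio_m))
  v34 <- x$v_curve$v[x$v_curve$n == 3]
  if (length(v34))
    cat(sprintf("  V_3/4 = %.3f (cutoff %.2f): %s\n", v34, x$cutoff,
                if (!is.na(v34) && v34 < x$cutoff) "3 genes sufficient"
                else "more than 3 genes recommended"))
  invisible(x)
}

#' @export
summary.genorm <- function(object, ...) {
  df <- data.frame(rank = seq_along(object$ranking), region = object$ranking,
                   M = unname(object$m_values[object$ranking]),
                   row.names = NULL)
  df$rank[df$region %in% object$final_trio] <- 1L
  structure(list(ranking = df, v_curve = object$v_curve,
                 sufficient_n = object$sufficient_n, trio_m = object$trio_m),
            class = "summary.genorm")
}

#' @export
print.summary.genorm <- function(x, ...) {
  print(x$ranking, row.names = FALSE)
  cat("\nV_n/n+1:\n")
  print(x$v_curve, row.names = FALSE)
  invisible(x)
}

#' @export
plot.genorm <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2), mar = c(7, 4, 2, 1))
  on.exit(graphics::par(op))
  m <- x$m_values[x$ranking]
  graphics::barplot(m, las = 2, ylab = "M (log2 units)",
                    main = "geNorm stability", cex.names = 0.7, ...)
  graphics::barplot(stats::setNames(x$v_curve$v,
                                    paste0("V", x$v_curve$n, "/", x$v_curve$n + 1)),
                    las = 2, ylab = "V_n/n+1", main = "NF pairwise variation")
  graphics::abline(h = x$cutoff, lty = 2)
  invisible(x)
}
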