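#' Model-based stability estimation (NormFinder-style)
#'
#' Decomposes log2 expression into a per-sample effect, a group-by-gene
#' deviation and gene-specific residual noise.  Within each group the
#' per-sample means over genes are subtracted (absorbing global loading
#' differences), leaving for gene i a group deviation estimate `d_ig` and
#' a residual variance `s2_ig`.  Because the subtracted sample mean
#' contains every gene's noise, `E[s2_i] = sigma2_i (1 - 2/n) +
#' mean(sigma2)/n` for n genes; the closed-form unbiased solution
#' `sigma2_i = (s2_i - S/(n(n-1))) * n/(n-2)` (S = sum of s2) is used,
#' truncated at zero.  Group deviations are centred per gene across groups
#' and shrunk toward zero by `gamma2 / (gamma2 + var(d))`, where `gamma2`
#' is a method-of-moments estimate of the true between-group deviation
#' variance.  The stability value of gene i is the group average of the
#' error budget incurred by using the gene as reference for a new sample:
#' `|d~_ig| + sqrt(sigma2_ig + shrunken var of d)`.  With no detectable
#' between-group variation (`gamma2 = 0`) this reduces exactly to the
#' single-group measure `sqrt(sigma2_i)`.  Lower is more stable.
#'
#' @param q samples x regions quantity matrix (see [quantify()]).
#' @param groups named sample-to-group map; defaults to the matrix's
#'   `groups` attribute.  Ignored in single-group mode.
#' @param mode `"multi_group"` (default; needs >= 2 groups with >= 2
#'   samples each) or `"single_group"` (ranking by corrected intra-group
#'   variance only).
#' @return Object of class `normfinder`: `stability` (rho per region),
#'   `ranking`, `intra_var` (sigma2 per region x group), `inter_dev`
#'   (shrunken d per region x group), `best_region`, and in multi-group
#'   mode `best_pair` with its combined stability.
#' @export
normfinder <- function(q, groups = NULL, mode = c("multi_group", "single_group")) {
  mode <- match.arg(mode)
  q <- structure(as_quantity_matrix(q), mask = attr(q, "mask"),
                 groups = attr(q, "groups"))
  L <- log2_quantities(q)
  if (ncol(L) < 3) stop("at least 3 regions required", call. = FALSE)
  if (mode == "single_group") {
    groups <- stats::setNames(rep("all", nrow(L)), rownames(L))
  } else {
    groups <- resolve_groups(q, groups)
    if (is.null(groups))
      stop("multi_group mode needs a sample-to-group map", call. = FALSE)
    names(groups) <- rownames(L)
    tab <- table(groups)
    if (length(tab) < 2)
      stop("multi_group mode needs at least 2 groups", call. = FALSE)
    small <- names(tab)[tab < 2]
    if (length(small))
      stop("insufficient data: group '", small[1], "' has fewer than 2 samples",
           call. = FALSE)
  }
  gl <- split(seq_len(nrow(L)), groups[rownames(L)])
  G <- length(gl)
  regions <- colnames(L)
  R <- length(regions)
  dn <- list(regions, names(gl))
  zbar <- sig2 <- cvar <- matrix(NA_real_, R, G, dimnames = dn)
  for (g in seq_len(G)) {
    X <- L[gl[[g]], , drop = FALSE]
    n_g <- nrow(X)
    z <- X - rowMeans(X, na.rm = TRUE)
    m <- colSums(!is.na(z))
    use <- m >= 2
    n_eff <- sum(use)
    if (n_eff < 3)
      stop("group '", names(gl)[g], "' has fewer than 3 usable regions",
           call. = FALSE)
    d <- colMeans(z, na.rm = TRUE)
    resid <- sweep(z, 2, d)
    s2 <- colSums(resid^2, na.rm = TRUE) / pmax(m - 1L, 1L)
    S <- sum(s2[use])
    sg <- rep(NA_real_, R)
    sg[use] <- pmax((s2[use] - S / (n_eff * (n_eff - 1))) * n_eff / (n_eff - 2), 0)
    zbar[use, g] <- d[use]
    sig2[, g] <- sg
    cvar[, g] <- (sg * (1 - 2 / n_eff) + mean(sg[use]) / n_eff) / n_g
  }

  if (mode == "single_group") {
    rho <- sqrt(sig2[, 1])
    dmat <- inter_dev <- matrix(0, R, 1, dimnames = dn)
    gamma2 <- 0
  } else {
    dmat <- zbar - rowMeans(zbar, na.rm = TRUE)
    ms <- sum(dmat^2, na.rm = TRUE) / ((R - 1) * (G - 1))
    gamma2 <- max(0, ms - mean(cvar, na.rm = TRUE))
    shrink <- gamma2 / (gamma2 + cvar)
    shrink[!is.finite(shrink)] <- 0
    inter_dev <- dmat * shrink
    vtilde <- cvar * shrink
    rho <- rowMeans(abs(inter_dev) + sqrt(sig2 + vtilde), na.rm = TRUE)
  }
  names(rho) <- regions
  ranking <- names(sort(rho))
  res <- structure(list(stability = rho, ranking = ranking,
                        intra_var = sig2, inter_dev = inter_dev,
                        raw_dev = dmat,
                        var_dev = cvar, gamma2 = gamma2, mode = mode,
                        groups = groups,
                        best_region = ranking[1]),
                   class = "normfinder")
  if (mode == "multi_group") res$best_pair <- best_pair(res)
  res
}

#' Best two-gene combination under the model-based criterion
#'
#' Averaging two genes halves the error variance of the shared reference
#' and lets opposite-sign group deviations cancel; a pair's combined
#' stability is the group average of `|mean of shrunken d| +
#' sqrt((v_i + v_k)/4)`, where `v` is each gene's total error variance
#' (residual plus shrunken deviation variance).  Returns the minimizing
#' pair.
#'
#' @param result a multi-group [normfinder()] result.
#' @return list with `pair` (sorted region names) and `stability`.
#' @export
best_pair <- function(result) {
  stopifnot(inherits(result, "normfinder"))
  if (result$mode != "multi_group")
    stop("unsupported mode: pair selection is defined for grouped analysis",
         call. = FALSE)
  regions <- rownames(result$inter_dev)
  if (length(regions) < 2) stop("need at least 2 regions", call. = FALSE)
  shrink <- result$gamma2 / (result$gamma2 + result$var_dev)
  shrink[!is.finite(shrink)] <- 0
  vtot <- result$intra_var + result$var_dev * shrink
  best <- NULL
  best_val <- Inf
  for (i in seq_along(regions)[-length(regions)]) {
    for (k in (i + 1):length(regions)) {
      dpair <- (result$inter_dev[i, ] + result$inter_dev[k, ]) / 2
      vpair <- (vtot[i, ] + vtot[k, ]) / 4
      val <- mean(abs(dpair) + sqrt(vpair), na.rm = TRUE)
      if (val < best_val - 1e-15) {
        best_val <- val
        best <- sort(c(regions[i], regions[k]))
      }
    }
  }
  list(pair = best, stability = best_val)
}

#' @export
print.normfinder <- function(x, ...) {
  cat(sprintf("<normfinder> %s mode, %d regions, %d group(s)\n", x$mode,
              length(x$stability), ncol(x$intra_var)))
  cat(sprintf("  best region: %s (stability %.3f)\n", x$best_region,
              x$stability[x$best_region]))
  if (!is.null(x$best_pair))
    cat(sprintf("  best pair: %s + %s (stability %.3f)\n", x$best_pair$pair[1],
                x$best_pair$pair[2], x$best_pair$stability))
  invisible(x)
}

#' @export
summary.normfinder <- function(object, ...) {
  data.frame(rank = seq_along(object$ranking), region = object$ranking,
             stability = unname(object$stability[object$ranking]),
             row.names = NULL)
}

#' @export
plot.normfinder <- function(x, ...) {
  op <- graphics::par(mar = c(7, 4, 2, 1))
  on.exit(graphics::par(op))
  graphics::barplot(x$stability[x$ranking], las = 2, cex.names = 0.7,
                    ylab = "stability value", main = "NormFinder", ...)
  invisible(x)
}
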