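# Independent brute-force oracles, deliberately written as plain double
# loops with hand-rolled sums so they share no code path with the package.

oracle_sd <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  m <- sum(x) / n
  sqrt(sum((x - m)^2) / (n - 1))
}

# geNorm V_jk by direct definition
oracle_v <- function(q, j, k) {
  oracle_sd(log2(q[, j] / q[, k]))
}

# geNorm M over an active set by direct definition
oracle_m <- function(q, active = colnames(q)) {
  out <- numeric(length(active))
  names(out) <- active
  for (j in active) {
    acc <- 0
    for (k in setdiff(active, j)) acc <- acc + oracle_v(q, j, k)
    out[j] <- acc / (length(active) - 1)
  }
  out
}

# NF_n / V_n/n+1 recomputed from scratch geometric means
oracle_nf <- function(q, regions) {
  apply(q[, regions, drop = FALSE], 1, function(x) prod(x)^(1 / length(x)))
}

oracle_v_curve <- function(q, ranked) {
  R <- length(ranked)
  vapply(2:(R - 1), function(n) {
    a <- oracle_nf(q, ranked[seq_len(n)])
    b <- oracle_nf(q, ranked[seq_len(n + 1)])
    oracle_sd(log2(a / b))
  }, numeric(1))
}

# delta-Ct pair SD and mean SD by direct definition
oracle_deltact <- function(m) {
  nm <- colnames(m)
  R <- length(nm)
  ps <- matrix(0, R, R, dimnames = list(nm, nm))
  for (j in 1:(R - 1)) for (k in (j + 1):R) {
    ps[j, k] <- ps[k, j] <- oracle_sd(m[, j] - m[, k])
  }
  list(pair_sd = ps, mean_sd = rowSums(ps) / (R - 1))
}

# NormFinder intra-group variances via the unbiasedness linear system:
# E[s2_i] = sig2_i (1 - 2/n) + sum(sig2)/n^2, solved numerically -- an
# independent route to the estimator (the package uses the closed form).
oracle_normfinder_sigma2 <- function(X) {
  n <- ncol(X)
  s2 <- numeric(n)
  for (i in seq_len(n)) {
    z <- numeric(nrow(X))
    for (j in seq_len(nrow(X))) z[j] <- X[j, i] - sum(X[j, ]) / n
    zbar <- sum(z) / nrow(X)
    s2[i] <- sum((z - zbar)^2) / (nrow(X) - 1)
  }
  A <- matrix(1 / n^2, n, n)
  diag(A) <- (1 - 2 / n) + 1 / n^2
  pmax(solve(A, s2), 0)
}

# random positive quantity matrix (log-normal, optional sample loading)
rand_q <- function(ns, nr, sd = 0.5, loading_sd = 1) {
  L <- matrix(rnorm(ns * nr, 0, sd), ns, nr) + rnorm(ns, 0, loading_sd)
  dimnames(L) <- list(sprintf("s%02d", seq_len(ns)),
                      sprintf("g%02d", seq_len(nr)))
  2^L
}

# tiny well-level table builder
make_wells <- function(samples, groups, regions, ct_fun, n_rep = 3) {
  rows <- expand.grid(sample_id = samples, region = regions,
                      replicate = seq_len(n_rep), stringsAsFactors = FALSE)
  rows$group_id <- groups[rows$sample_id]
  rows$ct <- mapply(ct_fun, rows$sample_id, rows$region, rows$replicate)
  rows
}
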