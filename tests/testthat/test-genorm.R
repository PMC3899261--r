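test_that("pairwise variation: hand-computed values and symmetry", {
  q <- cbind(A = c(1, 2, 4), B = c(2, 4, 8), C = c(1, 1, 1))
  rownames(q) <- paste0("s", 1:3)
  expect_equal(pairwise_variation(q, "A", "B"), 0)       # proportional genes
  expect_equal(pairwise_variation(q, "A", "C"), 1.0)     # sd of (0,1,2), n-1
  set.seed(11)
  r <- rand_q(8, 5)
  for (p in list(c(1, 2), c(2, 5), c(3, 4)))
    expect_identical(pairwise_variation(r, p[1], p[2]),
                     pairwise_variation(r, p[2], p[1]))
  expect_error(pairwise_variation(q[1, , drop = FALSE], "A", "B"),
               "insufficient")
})

test_that("M values match the 3-gene worked example and degenerate cases", {
  q <- cbind(A = c(1, 2, 4), B = c(2, 4, 8), C = c(1, 1, 1))
  rownames(q) <- paste0("s", 1:3)
  expect_equal(m_value(q, "A"), 0.5)
  expect_equal(m_value(q, "B"), 0.5)
  expect_equal(m_value(q, "C"), 1.0)
  expect_error(m_value(q, "A", active = c("A", "B")), "at least 3")

  same <- cbind(A = c(1, 2, 4), B = c(1, 2, 4), C = c(1, 2, 4))
  rownames(same) <- paste0("s", 1:3)
  expect_equal(unname(vapply(colnames(same), m_value, numeric(1), q = same)),
               rep(0, 3))
})

test_that("M agrees with a brute-force double-loop oracle on random matrices", {
  set.seed(21)
  for (i in 1:5) {
    q <- rand_q(8, 10)
    g <- genorm(q)
    m_impl <- vapply(colnames(q), m_value, numeric(1), q = q)
    expect_equal(m_impl, oracle_m(q), tolerance = 1e-12)
    # elimination-stage M values agree with a from-scratch recomputation
    active <- colnames(q)
    for (step in seq_along(g$elimination_order)) {
      mo <- oracle_m(q[, active, drop = FALSE])
      removed <- g$elimination_order[step]
      expect_equal(unname(g$m_values[removed]), unname(mo[removed]),
                   tolerance = 1e-12)
      active <- setdiff(active, removed)
    }
  }
})

test_that("M and V are invariant to per-sample global scaling", {
  set.seed(5)
  q <- rand_q(10, 6)
  scaled <- q * runif(10, 0.1, 10)   # row-wise loading
  expect_equal(vapply(colnames(q), m_value, numeric(1), q = q),
               vapply(colnames(q), m_value, numeric(1), q = scaled),
               tolerance = 1e-12)
})

test_that("stepwise elimination: proportional pair survives, tie-break deterministic", {
  set.seed(9)
  base <- 2^rnorm(10, 0, 1)
  q <- cbind(g1 = base, g2 = 3 * base,                       # exact proportional pair
             g3 = base * 2^rnorm(10, 0, 0.6),
             g4 = base * 2^rnorm(10, 0, 0.8),
             g5 = base * 2^rnorm(10, 0, 1.0))
  rownames(q) <- paste0("s", 1:10)
  g <- genorm(q)
  expect_true(all(c("g1", "g2") %in% g$final_trio))

  # exact tie: four regions in two proportional pairs; removal is the
  # lexicographically last name, recorded in the trace
  qt <- cbind(a = base, b = 2 * base,
              c = base * 2^rnorm(10, 0, 0.5))
  qt <- cbind(qt, d = qt[, "c"] * 2)
  rownames(qt) <- paste0("s", 1:10)
  gt <- genorm(qt)
  expect_equal(gt$elimination_order[1], "d")
  expect_true(gt$trace[[1]]$tie)
})

test_that("stepwise ranking is invariant to region input order", {
  set.seed(14)
  q <- rand_q(9, 7)
  g1 <- genorm(q)
  g2 <- genorm(q[, sample(colnames(q))])
  expect_identical(g1$ranking, g2$ranking)
  expect_equal(g1$m_values, g2$m_values[names(g1$m_values)], tolerance = 1e-12)
})

test_that("an injected high-noise region is eliminated first", {
  hits <- 0
  for (seed in 1:50) {
    set.seed(seed)
    base <- rnorm(12, 0, 1)
    L <- sapply(1:5, function(i) base + rnorm(12, 0, 0.05))
    L <- cbind(L, base + rnorm(12, 0, 1))   # the unstable region
    colnames(L) <- paste0("g", 1:6)
    rownames(L) <- paste0("s", 1:12)
    g <- genorm(2^L)
    if (g$elimination_order[1] == "g6") hits <- hits + 1
  }
  expect_gte(hits, 48)
})

test_that("normalization factor: geometric mean, scale equivariance, errors", {
  q <- matrix(c(2, 4, 8), 1, 3, dimnames = list("s1", c("a", "b", "c")))
  expect_equal(unname(normalization_factor(q, c("a", "b", "c"))), 4.0)
  q1 <- matrix(1, 1, 3, dimnames = list("s1", c("a", "b", "c")))
  expect_equal(unname(normalization_factor(q1, c("a", "b", "c"))), 1.0)

  set.seed(2)
  r <- rand_q(6, 4)
  nf <- normalization_factor(r, colnames(r)[1:3])
  r2 <- r; r2[, 1] <- r2[, 1] * 8
  expect_equal(normalization_factor(r2, colnames(r)[1:3]), nf * 8^(1 / 3),
               tolerance = 1e-12)
  r3 <- r; r3[2, 1] <- -1
  expect_error(normalization_factor(r3, colnames(r)[1:3]), "positive")
  expect_error(normalization_factor(r, colnames(r)[1]), "at least 2")
})

test_that("V_n/n+1 matches from-scratch NF recomputation and cutoff default", {
  set.seed(31)
  for (i in 1:5) {
    q <- rand_q(10, 6)
    ranked <- genorm(q)$ranking
    v <- v_pairwise_nf(q, ranked)
    expect_equal(v$v_curve$v, oracle_v_curve(q, ranked), tolerance = 1e-12)
  }
  expect_equal(formals(v_pairwise_nf)$cutoff, 0.15)

  const <- matrix(5, 6, 4, dimnames = list(paste0("s", 1:6), paste0("g", 1:4)))
  v0 <- v_pairwise_nf(const, colnames(const))
  expect_equal(v0$v_curve$v, c(0, 0))
  expect_equal(v0$sufficient_n, 2L)
})

test_that("masked cells are excluded pairwise-complete", {
  set.seed(8)
  q <- rand_q(8, 4)
  mask <- matrix(FALSE, 8, 4, dimnames = dimnames(q))
  mask[1:3, 2] <- TRUE
  qm <- q; attr(qm, "mask") <- mask
  v_masked <- pairwise_variation(qm, 1, 2)
  expect_equal(v_masked, oracle_sd(log2(q[4:8, 1] / q[4:8, 2])),
               tolerance = 1e-12)
  # unmasked pairs unaffected
  expect_equal(pairwise_variation(qm, 1, 3), pairwise_variation(q, 1, 3))
})
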