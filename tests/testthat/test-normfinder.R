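test_that("intra-group variance estimates match the ANOVA linear-system oracle", {
  # fixed small matrix: 6 samples x 3 regions, one group
  set.seed(17)
  X <- matrix(rnorm(18, 0, 1), 6, 3) + rnorm(6, 0, 2)
  dimnames(X) <- list(paste0("s", 1:6), paste0("g", 1:3))
  nf <- normfinder(2^X, mode = "single_group")
  expect_equal(unname(nf$intra_var[, 1]), unname(oracle_normfinder_sigma2(X)),
               tolerance = 1e-10)

  # and per group in multi-group mode, on random 4-group data
  for (i in 1:5) {
    q <- rand_q(12, 5)
    groups <- setNames(rep(c("a", "b", "c"), each = 4), rownames(q))
    res <- normfinder(q, groups)
    L <- log2(q)
    for (g in c("a", "b", "c"))
      expect_equal(unname(res$intra_var[, g]),
                   unname(oracle_normfinder_sigma2(L[groups == g, ])),
                   tolerance = 1e-10)
  }
})

test_that("single-group ranking equals ordering by residual variance", {
  set.seed(23)
  for (i in 1:10) {
    q <- rand_q(10, 6)
    res <- normfinder(q, mode = "single_group")
    L <- log2(q)
    z <- L - rowMeans(L)
    resid_var <- apply(z, 2, var)
    expect_identical(res$ranking, names(sort(resid_var)))
  }
})

test_that("a zero-residual gene is most stable in single-group mode", {
  set.seed(3)
  sample_eff <- rnorm(12, 0, 1)
  L <- sapply(1:5, function(i) sample_eff + i + rnorm(12, 0, 0.4))
  L <- cbind(L, clean = sample_eff + 2)     # exactly sample effect + constant
  colnames(L)[1:5] <- paste0("g", 1:5)
  rownames(L) <- paste0("s", 1:12)
  res <- normfinder(2^L, mode = "single_group")
  expect_identical(res$best_region, "clean")
  expect_equal(unname(res$stability["clean"]), 0)
})

test_that("stability is invariant to per-sample global scaling", {
  set.seed(6)
  q <- rand_q(12, 5)
  groups <- setNames(rep(c("a", "b"), each = 6), rownames(q))
  r1 <- normfinder(q, groups)
  r2 <- normfinder(q * runif(12, 0.05, 20), groups)
  expect_equal(r1$stability, r2$stability, tolerance = 1e-12)
  expect_equal(r1$intra_var, r2$intra_var, tolerance = 1e-12)
})

test_that("group deviations are centred (sum to zero within group)", {
  set.seed(12)
  q <- rand_q(12, 6)
  groups <- setNames(rep(c("a", "b", "c"), each = 4), rownames(q))
  res <- normfinder(q, groups)
  expect_lt(max(abs(colSums(res$raw_dev))), 1e-10)
  # single-group mode has all deviations identically zero
  rs <- normfinder(q, mode = "single_group")
  expect_true(all(rs$inter_dev == 0))
})

test_that("a region shifted in one group only is ranked last", {
  hits <- 0
  for (seed in 1:50) {
    set.seed(seed)
    L <- matrix(rnorm(12 * 6, 0, 0.05), 12, 6) + rnorm(12, 0, 1)
    dimnames(L) <- list(paste0("s", 1:12), paste0("g", 1:6))
    groups <- setNames(rep(c("a", "b"), each = 6), rownames(L))
    L[groups == "b", "g6"] <- L[groups == "b", "g6"] + 1   # +1 log2 shift
    res <- normfinder(2^L, groups)
    if (res$ranking[length(res$ranking)] == "g6") hits <- hits + 1
  }
  expect_gte(hits, 48)
})

test_that("shrunken deviations recover an injected group shift", {
  set.seed(77)
  n_genes <- 17
  L <- matrix(rnorm(100 * n_genes, 0, 0.2), 100, n_genes) + rnorm(100, 0, 1)
  dimnames(L) <- list(paste0("s", 1:100), paste0("g", 1:n_genes))
  groups <- setNames(rep(c("a", "b"), each = 50), rownames(L))
  shift <- 1
  L[groups == "b", "g1"] <- L[groups == "b", "g1"] + shift
  res <- normfinder(2^L, groups)
  est <- res$inter_dev["g1", "b"] - res$inter_dev["g1", "a"]
  # identifiable interaction contrast: shift reduced by the 1/n centering
  expect_equal(est, shift * (1 - 1 / n_genes), tolerance = 0.1)
})

test_that("best pair exploits cancellation and is lower than either member", {
  set.seed(41)
  base <- rnorm(16, 0, 1)
  groups <- setNames(rep(c("a", "b"), each = 8), paste0("s", 1:16))
  mk <- function(shift_b, sd = 0.15) {
    x <- base + rnorm(16, 0, sd)
    x[groups == "b"] <- x[groups == "b"] + shift_b
    x
  }
  L <- cbind(up = mk(0.8), down = mk(-0.8), n1 = mk(0))
  rownames(L) <- names(groups)
  res <- normfinder(2^L, groups)
  bp <- res$best_pair
  expect_setequal(bp$pair, c("up", "down"))
  expect_lt(bp$stability, res$stability["up"])
  expect_lt(bp$stability, res$stability["down"])
  expect_identical(bp$pair, sort(bp$pair))   # (a,b) == (b,a): reported sorted
})

test_that("pair stability of iid equal-variance genes is ~ single / sqrt(2)", {
  set.seed(55)
  ratios <- replicate(100, {
    L <- matrix(rnorm(80 * 4, 0, 0.3), 80, 4) + rnorm(80, 0, 1)
    dimnames(L) <- list(paste0("s", 1:80), paste0("g", 1:4))
    groups <- setNames(rep(c("a", "b"), each = 40), rownames(L))
    res <- normfinder(2^L, groups)
    res$best_pair$stability / mean(res$stability)
  })
  expect_lt(abs(mean(ratios) - 1 / sqrt(2)), 0.08)
})

test_that("mode contracts: errors name the offending group, pair needs groups", {
  q <- rand_q(5, 4)
  groups <- setNames(c("a", "a", "b", "b", "lone"), rownames(q))
  expect_error(normfinder(q, groups), "lone")
  rs <- normfinder(q, mode = "single_group")
  expect_error(best_pair(rs), "unsupported mode")
  expect_error(normfinder(rand_q(6, 2), mode = "single_group"), "3 regions")
})

test_that("increasing pure noise on one region increases its stability value", {
  mean_rho <- sapply(c(0.05, 0.2, 0.5, 1.0), function(s) {
    vals <- vapply(1:40, function(seed) {
      set.seed(seed)
      base <- rnorm(16, 0, 1)
      groups <- setNames(rep(c("a", "b"), each = 8), paste0("s", 1:16))
      L <- sapply(1:5, function(i) {
        x <- base + rnorm(16, 0, 0.1)
        if (i <= 2) x[groups == "b"] <- x[groups == "b"] + c(0.4, -0.4)[i]
        x
      })
      eps <- rnorm(16)                      # same draws, scaled by s
      L <- cbind(L, probe = base + s * eps)
      colnames(L)[1:5] <- paste0("g", 1:5)
      rownames(L) <- names(groups)
      normfinder(2^L, groups)$stability["probe"]
    }, numeric(1))
    mean(vals)
  })
  expect_true(all(diff(mean_rho) > 0))
})
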