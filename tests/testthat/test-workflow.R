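sim_with_targets <- function(seed = 1) {
  simulate_qpcr(preset_study_like(include_targets = TRUE), seed = seed)
}

test_that("pipeline report contains every stage's results", {
  sim <- simulate_qpcr(preset_study_like(), seed = 1)
  rep <- run_screening_pipeline(sim$ct, sim$dilutions, study_config(keep = 6))
  expect_s3_class(rep, "refgene_report")
  expect_length(rep$screening$kept, 6)
  expect_length(rep$rankings$genorm$overall$final_trio, 3)
  expect_true(is.character(rep$rankings$normfinder$overall$best_region))
  expect_length(rep$rankings$normfinder$overall$best_pair$pair, 2)
  expect_match(rep$selection$verdict, "genes")
  expect_true(all(c("FB", "FO", "FF") %in% names(rep$rankings$genorm$per_group)))
  # per-group rankings reuse the global curves: quantities are shared
  expect_identical(colnames(rep$quantities), rep$screening$kept)
})

test_that("keep = all bypasses stage 1", {
  sim <- simulate_qpcr(preset_study_like(), seed = 2)
  rep <- run_screening_pipeline(sim$ct, sim$dilutions, study_config(keep = Inf))
  expect_length(rep$screening$kept, 17)
})

test_that("a low V_3/4 yields the '3 genes sufficient' verdict", {
  # three near-proportional stable genes plus a fourth: V tiny by design
  spec <- sim_spec(groups = c(A = 4L, B = 4L),
                   regions = data.frame(
                     region = paste0("g", 1:5, "_utr"),
                     base_ct = c(21, 22, 23, 24, 25),
                     noise_sd = c(0.02, 0.02, 0.02, 0.02, 0.4),
                     efficiency = 1),
                   loading_sd = 0.5, replicate_sd = 0.01)
  sim <- simulate_qpcr(spec, seed = 3)
  rep <- run_screening_pipeline(sim$ct, sim$dilutions,
                                study_config(keep = Inf))
  expect_lt(rep$selection$v, 0.15)
  expect_identical(rep$selection$verdict, "3 genes sufficient")
})

test_that("normalize_target: self-normalization and loading cancellation", {
  set.seed(13)
  q <- rand_q(10, 4)
  refs <- colnames(q)[1:3]
  target <- cbind(q, tgt = apply(q[, refs], 1, function(x) prod(x)^(1 / 3)))
  ne <- normalize_target(target, "tgt", refs)
  expect_equal(unname(ne$values), rep(1, 10), tolerance = 1e-12)

  scaled <- target * runif(10, 0.2, 5)
  ne2 <- normalize_target(scaled, "tgt", refs)
  expect_equal(ne$values, ne2$values, tolerance = 1e-12)
  expect_error(normalize_target(target, "tgt", c("tgt", refs)),
               "configuration error")
})

test_that("a seasonal peak survives normalization by best and worst references", {
  hits_best <- hits_worst <- 0
  for (seed in 1:20) {
    sim <- sim_with_targets(seed)
    m <- ct_matrix(sim$ct)
    curves <- fit_standard_curves(sim$dilutions)
    q <- quantify(m, curves)
    fb <- which(attr(q, "groups") == "FB")
    best <- c("HIS_utr1", "SAND_utr", "TIP_utr")
    worst <- c("bTUB_utr2", "ACT_utr2", "bTUB_utr3")
    nb <- normalize_target(q, "CBF2_utr", best)
    nw <- normalize_target(q, "CBF2_utr", worst)
    if (names(which.max(nb$values[fb])) == "FB_3") hits_best <- hits_best + 1
    if (names(which.max(nw$values[fb])) == "FB_3") hits_worst <- hits_worst + 1
  }
  expect_gte(hits_best, 19)
  expect_gte(hits_worst, 18)
})

test_that("robustness comparison: identity and scale-only reference sets", {
  set.seed(23)
  q <- rand_q(12, 6)
  groups <- setNames(rep(c("a", "b", "c"), each = 4), rownames(q))
  attr(q, "groups") <- groups
  refs <- colnames(q)[1:3]
  tgt <- colnames(q)[6]
  same <- robustness_compare(q, tgt, refs, refs)
  expect_equal(unname(same$ratio), rep(1, 12), tolerance = 1e-12)
  expect_equal(same$log_correlation, 1, tolerance = 1e-9)

  expect_error(robustness_compare(q, tgt, c(tgt, refs[1]), refs),
               "configuration error")
})

test_that("scale-only different reference sets give constant ratio, correlation 1", {
  set.seed(33)
  q <- rand_q(10, 7)
  groups <- setNames(rep(c("a", "b"), each = 5), rownames(q))
  attr(q, "groups") <- groups
  # worst set = best set with each column rescaled by a constant
  q[, 4:6] <- sweep(q[, 1:3], 2, c(2, 5, 0.3), `*`)
  colnames(q)[4:6] <- c("w1", "w2", "w3")
  cmp <- robustness_compare(q, colnames(q)[7], colnames(q)[1:3],
                            c("w1", "w2", "w3"))
  expect_lt(diff(range(cmp$ratio)), 1e-12)
  expect_equal(cmp$log_correlation, 1, tolerance = 1e-9)
})

test_that("CV of normalized references: degenerate, invariance, oracle", {
  const <- matrix(3, 8, 4, dimnames = list(paste0("s", 1:8), paste0("g", 1:4)))
  cv0 <- cv_of_normalized(const, colnames(const)[1:3])
  expect_equal(unname(cv0$per_region), rep(0, 3))

  set.seed(43)
  q <- rand_q(10, 5)
  refs <- colnames(q)[1:3]
  cv1 <- cv_of_normalized(q, refs)
  cv2 <- cv_of_normalized(q * runif(10, 0.1, 9), refs)
  expect_equal(cv1$per_region, cv2$per_region, tolerance = 1e-12)

  nf <- oracle_nf(q, refs)
  expected <- vapply(refs, function(r) {
    x <- q[, r] / nf
    oracle_sd(x) / mean(x)
  }, numeric(1))
  expect_equal(cv1$per_region, expected, tolerance = 1e-12)
  expect_equal(cv1$mean_cv, mean(expected), tolerance = 1e-12)
})

test_that("clean data with a strict stability ordering: methods agree on the top 3", {
  agree <- 0
  for (seed in 1:30) {
    set.seed(seed)
    sds <- c(0.05, 0.06, 0.07, 0.4, 0.5, 0.6, 0.7)
    L <- sapply(sds, function(s) rnorm(16, 0, s)) + rnorm(16, 0, 1)
    dimnames(L) <- list(paste0("s", 1:16), paste0("g", 1:7))
    m <- 25 - L   # as Ct
    q <- 2^L
    groups <- setNames(rep(c("a", "b"), each = 8), rownames(L))
    top_g <- genorm(q)$final_trio
    top_n <- normfinder(q, groups)$ranking[1:3]
    top_d <- delta_ct_rank(m)$ranking[1:3]
    if (setequal(top_g, c("g1", "g2", "g3")) &&
        setequal(top_n, c("g1", "g2", "g3")) &&
        setequal(top_d, c("g1", "g2", "g3"))) agree <- agree + 1
  }
  expect_gte(agree, 27)
})

test_that("report writer emits the promised deterministic artifacts", {
  sim <- simulate_qpcr(preset_study_like(), seed = 9)
  rep <- run_screening_pipeline(sim$ct, sim$dilutions, study_config(keep = 6))
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_report(rep, d1)
  write_report(rep, d2)
  files <- c("report.json", "report.md", "genorm_ranking.csv",
             "genorm_v_curve.csv", "deltact_ranking.csv",
             "normfinder_ranking.csv")
  for (f in files) {
    expect_true(file.exists(file.path(d1, f)))
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
})
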