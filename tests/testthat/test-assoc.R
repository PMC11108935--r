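test_that("the two rank conventions handle ties as documented", {
  expect_equal(as.numeric(rank_values(c(10, 20, 20, 30), "averaged")),
               c(1, 2.5, 2.5, 4))
  expect_equal(as.numeric(rank_values(c(10, 20, 20, 30), "order_of_appearance")),
               c(1, 2, 3, 4))
  x <- c(3, 9, 27, 81)
  expect_equal(as.numeric(rank_values(x, "averaged")),
               as.numeric(rank_values(x, "order_of_appearance")))
  r <- rank_values(c(1, NA, 2))
  expect_true(is.na(r[2]))
  expect_equal(attr(r, "n_missing"), 1L)
  expect_error(rank_values(numeric(0)), "no values")
})

test_that("spearman is pearson on mid-ranks with the t-approximate p-value", {
  expect_equal(spearman_test(1:10, (1:10)^3)$statistic, 1)
  expect_equal(spearman_test(1:5, 5:1)$statistic, -1)
  set.seed(25)
  for (i in 1:10) {
    x <- rnorm(30); y <- rnorm(30)
    st <- spearman_test(x, y)
    expect_equal(st$statistic, cor(rank(x), rank(y)), tolerance = 1e-12)
    tval <- st$statistic * sqrt(28 / (1 - st$statistic^2))
    expect_equal(st$p_value, 2 * pt(-abs(tval), 28), tolerance = 1e-12)
  }
  # pairwise deletion
  x <- c(1:10, NA); y <- c(NA, 2:11)
  expect_equal(spearman_test(x, y)$n_used, 9)
  # degenerate ranks
  expect_true(is.na(spearman_test(rep(1, 5), 1:5)$statistic))
})

test_that("mann-whitney U has the right null center, separation bound and symmetry", {
  a <- c(1, 2, 3, 4); b <- c(1, 2, 3, 4)
  mw <- suppressWarnings(mann_whitney_test(a, b))
  expect_equal(mw$statistic, length(a) * length(b) / 2)
  expect_gt(mw$p_value, 0.9)
  sep <- mann_whitney_test(c(1, 2, 3), c(10, 11, 12))
  expect_equal(sep$statistic, 0)
  set.seed(26)
  g1 <- rnorm(15); g2 <- rnorm(12, 1)
  m12 <- mann_whitney_test(g1, g2)
  m21 <- mann_whitney_test(g2, g1)
  expect_equal(m12$p_value, m21$p_value, tolerance = 1e-12)
  expect_equal(m12$statistic + m21$statistic, 15 * 12)
})

test_that("kruskal-wallis is zero for identical groups and detects shifts", {
  v <- rep(c(1, 2, 3), 3)
  g <- factor(rep(letters[1:3], each = 3))
  expect_equal(kruskal_wallis_test(v, g)$statistic, 0)
  set.seed(27)
  v2 <- c(rnorm(20), rnorm(20, 3), rnorm(20, 6))
  g2 <- factor(rep(letters[1:3], each = 20))
  expect_lt(kruskal_wallis_test(v2, g2)$p_value, 1e-6)
  expect_error(kruskal_wallis_test(1:3, factor(rep("a", 3))), "2 groups")
})

test_that("benjamini-hochberg step-up matches the hand-worked example", {
  expect_equal(bh_fdr(0.03)$q, 0.03)
  adj <- bh_fdr(c(0.01, 0.02, 0.03, 0.04))
  expect_equal(adj$q, rep(0.04, 4))
  expect_true(all(adj$significant))
  set.seed(28)
  p <- runif(50)^2
  q <- bh_fdr(p)$q
  expect_true(all(q >= p))
  expect_equal(order(q[order(p)]), 1:50)  # sorting by p sorts by q
  # BH never rejects more than unadjusted testing at the same threshold
  expect_lte(sum(q <= 0.1), sum(p <= 0.1))
})

test_that("the centered moving average respects the missing-slot budget", {
  expect_equal(centered_moving_average(rep(7, 50)), rep(7, 50))
  # linear series: interior windows i-10..i+9 average to i - 0.5
  v <- as.numeric(1:100)
  sm <- centered_moving_average(v)
  expect_equal(sm[11:91], (11:91) - 0.5)
  # independently recompute every position with a direct loop
  direct <- sapply(seq_along(v), function(i) {
    idx <- (i - 10):(i + 9)
    ok <- idx >= 1 & idx <= 100
    if (20 - sum(ok) > 10) NA_real_ else mean(v[idx[ok]])
  })
  expect_equal(sm, direct)
  # a run of 11 missing values suppresses the windows that hold all of them
  w <- rep(1, 60); w[20:30] <- NA
  smw <- centered_moving_average(w)
  expect_true(all(is.na(smw[21:30])))   # windows covering all 11 NAs
  expect_false(anyNA(smw[c(1:20, 31:60)]))
})

test_that("ranked regression recovers slope 1, slope -1, and equals rho on full ranks", {
  expect_equal(ranked_regression(1:20, 1:20), list(slope = 1, intercept = 0))
  rr <- ranked_regression(1:15, 15:1)
  expect_equal(rr$slope, -1)
  expect_equal(rr$intercept, 16)
  set.seed(29)
  x <- sample(40); y <- sample(40)
  expect_equal(ranked_regression(x, y)$slope, cor(x, y, method = "spearman"),
               tolerance = 1e-12)
  expect_error(ranked_regression(rep(2, 5), 1:5), "zero variance")
})

test_that("the validation battery types tests, families FDR, and flags targets", {
  set.seed(30)
  n <- 228
  L <- matrix(rnorm(n * 3), n, 3)
  colnames(L) <- paste0("dim", 1:3)
  covs <- data.frame(
    hit = 0.6 * L[, 1] + sqrt(1 - 0.36) * rnorm(n),   # tied to dimension 1 only
    noise = rnorm(n),
    grp = factor(sample(c("a", "b"), n, TRUE)),
    multi = factor(sample(c("p", "q", "r"), n, TRUE))
  )
  res <- run_validation_battery(L, covs,
    families = list(f1 = "hit", f2 = "noise", f3 = "grp", f4 = "multi"))
  expect_equal(sum(res$family == "f1"), 3)  # 3 dimensions x 1 covariate
  hit <- res[res$family == "f1", ]
  expect_true(hit$significant[hit$dimension == 1])
  expect_false(any(hit$significant[hit$dimension != 1]))
  expect_true(all(res$test[res$family == "f3"] == "mann_whitney"))
  expect_true(any(res$test[res$family == "f4"] == "kruskal_wallis"))
  expect_true(any(res$test[res$family == "f4"] == "mann_whitney_posthoc"))
  # q >= p within families
  expect_true(all(res$q_value >= res$p_value - 1e-12))
  expect_error(run_validation_battery(L, covs, families = list(f = "absent")),
               "unknown covariate")
  expect_error(run_validation_battery(L, covs,
               families = list(f = "hit", g = "hit")), "more than one family")
})
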