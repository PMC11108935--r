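test_that("preprocessing standardizes continuous and MCA-scales categorical columns", {
  set.seed(6)
  df <- data.frame(a = rnorm(50), b = runif(50),
                   g = factor(sample(c("x", "y"), 50, TRUE, prob = c(0.3, 0.7))))
  pp <- preprocess_mixed(df)
  expect_equal(colMeans(pp$M), rep(0, ncol(pp$M)), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(mean(pp$M[, "a"]^2), 1, tolerance = 1e-12)
  # binary variable block carries total inertia 1 regardless of level split
  expect_equal(sum(colMeans(pp$M[, 3:4]^2)), 1, tolerance = 1e-12)
  expect_equal(pp$total_inertia, 3, tolerance = 1e-12)
})

test_that("preprocessing rejects degenerate columns by name", {
  df <- data.frame(a = rep(1, 10), b = rnorm(10))
  expect_error(preprocess_mixed(df), "constant.*a")
  df2 <- data.frame(a = rnorm(10), g = factor(rep("only", 10)))
  expect_error(mixed_table(df2), "fewer than 2 levels")
})

test_that("FAMD equals population-standardized PCA on all-continuous tables", {
  for (s in 1:5) {
    set.seed(s)
    X <- matrix(rnorm(100), 20, 5)
    colnames(X) <- paste0("v", 1:5)
    fit <- suppressWarnings(famd(as.data.frame(X), ncp = 5))
    expect_equal(fit$eigenvalues, pca_pop_oracle(X)[seq_along(fit$eigenvalues)],
                 tolerance = 1e-8)
  }
})

test_that("duplicated standardized variables put all inertia on one dimension", {
  set.seed(7)
  v <- rnorm(30)
  fit <- suppressWarnings(famd(data.frame(a = v, b = v), ncp = 2))
  expect_equal(fit$eigenvalues[1], 2, tolerance = 1e-10)
  expect_lt(length(fit$eigenvalues), 2)  # rank 1: second eigenvalue is exactly null
  expect_equal(unname(fit$var_sq_cosines[, 1]), c(1, 1), tolerance = 1e-10)
})

test_that("a single binary variable yields eigenvalue 1 for any level split", {
  for (p in c(0.1, 0.35, 0.5)) {
    set.seed(100 + round(100 * p))
    g <- factor(c(rep("a", round(40 * p)), rep("b", 40 - round(40 * p))))
    fit <- suppressWarnings(famd(data.frame(g = g), ncp = 1))
    expect_equal(fit$eigenvalues[1], 1, tolerance = 1e-10)
  }
})

test_that("total inertia is conserved and donor contributions sum to 100", {
  set.seed(8)
  df <- data.frame(a = rnorm(60), b = rexp(60), c = rnorm(60),
                   g = factor(sample(letters[1:3], 60, TRUE)),
                   h = factor(sample(c("u", "v"), 60, TRUE)))
  fit <- suppressWarnings(famd(df, ncp = 6))
  # Kc + sum(levels - 1) = 3 + 2 + 1
  expect_equal(fit$total_inertia, 6, tolerance = 1e-8)
  expect_equal(sum(fit$eigenvalues), 6, tolerance = 1e-8)
  expect_equal(unname(colSums(fit$donor_contrib)), rep(100, fit$ncp),
               tolerance = 1e-6)
  # scores on distinct dimensions are uncorrelated under uniform weights
  cv <- crossprod(fit$scores) / fit$n
  expect_true(max(abs(cv[upper.tri(cv)])) < 1e-8)
  # squared cosines are proportions
  expect_true(all(fit$var_sq_cosines >= -1e-12 & fit$var_sq_cosines <= 1 + 1e-12))
})

test_that("eigenvalues are invariant to row order and sign orientation", {
  set.seed(9)
  df <- data.frame(a = rnorm(40), b = rnorm(40),
                   g = factor(sample(c("x", "y"), 40, TRUE)))
  fit <- suppressWarnings(famd(df, ncp = 3))
  perm <- sample(40)
  fit2 <- suppressWarnings(famd(df[perm, ], ncp = 3))
  expect_equal(fit$eigenvalues, fit2$eigenvalues, tolerance = 1e-10)
  flipped <- orient_dimensions(fit, c("a", "a", "a"))
  expect_equal(flipped$eigenvalues, fit$eigenvalues)
})

test_that("dimension selection applies a strict eigenvalue cutoff", {
  fit <- structure(list(eigenvalues = c(2.6, 1.7, 1.67, 1.2, 0.8), ncp = 5),
                   class = "famd")
  expect_equal(select_dimensions(fit, 1.5), 1:3)
  expect_equal(select_dimensions(fit, 3), integer(0))
  expect_equal(select_dimensions(fit, 0), 1:5)
})

test_that("orientation flips negative anchors, is idempotent, warns on zero anchor", {
  set.seed(10)
  df <- data.frame(a = rnorm(40), b = rnorm(40), c = rnorm(40))
  fit <- suppressWarnings(famd(df, ncp = 3))
  anch <- c("a", "b", "c")
  o1 <- orient_dimensions(fit, anch)
  for (s in 1:3) expect_gte(o1$var_correlations[anch[s], s], 0)
  o2 <- orient_dimensions(o1, anch)
  expect_equal(o2$scores, o1$scores)
  # manually zero a correlation to exercise the warning path
  fit0 <- fit
  fit0$var_correlations["a", 1] <- 0
  expect_warning(orient_dimensions(fit0, c("a")), "zero correlation")
})

test_that("variable summary has correct marginals", {
  set.seed(11)
  df <- data.frame(a = rnorm(50), b = rexp(50),
                   g = factor(sample(c("x", "y"), 50, TRUE)))
  fit <- suppressWarnings(famd(df, ncp = 3))
  sm <- variable_dimension_summary(fit)
  # contributions over variables sum to 100 per dimension
  agg <- tapply(sm$contribution, sm$dimension, sum)
  expect_equal(as.numeric(agg), rep(100, fit$ncp), tolerance = 1e-8)
  expect_true(all(is.na(sm$correlation[sm$variable == "g"])))
})
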