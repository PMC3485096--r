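test_that("collinear data are fitted with zero loss at any tau", {
  x <- 1:10
  for (tau in c(0.1, 0.5, 0.9)) {
    f <- quantile_fit(x, 2 * x + 1, tau)
    expect_equal(f$slope, 2)
    expect_equal(f$intercept, 1)
    expect_equal(f$objective, 0)
  }
})

test_that("the median fit attains the LAD point-pair enumeration minimum", {
  lad_oracle <- function(x, y) {
    best <- Inf
    n <- length(x)
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        if (x[i] == x[j]) next
        b <- (y[i] - y[j]) / (x[i] - x[j])
        a <- y[i] - b * x[i]
        best <- min(best, sum(rho_tau(y - a - b * x, 0.5)))
      }
    }
    best
  }
  set.seed(7)
  for (rep in 1:10) {
    n <- sample(5:15, 1)
    x <- rnorm(n); y <- rnorm(n)
    f <- quantile_fit(x, y, 0.5)
    expect_lt(abs(f$objective - lad_oracle(x, y)), 1e-8)
  }
})

test_that("compiled and reference backends agree, including tied data", {
  set.seed(9)
  for (rep in 1:20) {
    n <- sample(5:60, 1)
    x <- sample(round(rnorm(n), 1))       # ties in x
    y <- round(rnorm(n), 1)               # ties in y
    if (max(x) == min(x)) next
    for (tau in c(0.25, 0.5, 0.8)) {
      a <- quantile_fit(x, y, tau)
      b <- quantile_fit(x, y, tau, method = "reference")
      expect_lt(abs(a$objective - b$objective), 1e-10)
      expect_lt(abs(a$slope - b$slope), 1e-8)
    }
  }
})

test_that("the fit matches quantreg's exact simplex solution", {
  set.seed(13)
  for (tau in c(0.25, 0.5, 0.75, 0.9)) {
    x <- runif(80); y <- x + rnorm(80)
    f <- quantile_fit(x, y, tau)
    rq <- quantreg::rq(y ~ x, tau = tau)
    expect_lt(abs(f$objective - sum(rho_tau(resid(rq), tau))), 1e-8)
  }
})

test_that("degenerate inputs are rejected", {
  expect_error(quantile_fit(c(1, 1, 1), c(1, 2, 3)), "constant")
  expect_error(quantile_fit(1:2, 1:2), "at least 3")
  expect_error(quantile_fit(1:5, 1:5, tau = 0), "tau")
  expect_error(quantile_fit(1:5, 1:5, tau = 1.2), "tau")
})

test_that("a null slope is recovered on average", {
  set.seed(17)
  slopes <- replicate(200, quantile_fit(runif(30), rnorm(30), 0.5)$slope)
  expect_lt(abs(mean(slopes)), 3 * sd(slopes) / sqrt(200))
})

test_that("permutation p-values respect their bounds and relabeling invariance", {
  set.seed(23)
  a <- setNames(runif(10), sprintf("s%02d", 1:10))
  e <- setNames(rnorm(10, sd = 0.2), names(a))
  Y <- outer(e, e, "+")
  pairs <- make_pair_fixture(a, Y)
  res <- species_permutation_pvalue(pairs, "attr", "y", B_perm = 99, seed = 5)
  expect_gte(res$p_perm, 1 / 100)
  expect_lte(res$p_perm, 1)

  # renaming species leaves the p-value unchanged (same seed)
  a2 <- setNames(a, sprintf("t%02d", 1:10))
  Y2 <- Y; dimnames(Y2) <- list(names(a2), names(a2))
  pairs2 <- make_pair_fixture(a2, Y2)
  res2 <- species_permutation_pvalue(pairs2, "attr", "y", B_perm = 99, seed = 5)
  expect_identical(res$p_perm, res2$p_perm)

  # perfectly predictive structure gives the minimal attainable p
  D <- abs(outer(a, a, "-"))
  pairs3 <- make_pair_fixture(a, D) # response IS the predictor distance
  res3 <- species_permutation_pvalue(pairs3, "attr", "y", B_perm = 199, seed = 7)
  expect_equal(res3$p_perm, 1 / 200)

  # constant species attribute -> no null to permute
  pairs4 <- make_pair_fixture(setNames(rep(1, 10), names(a)), Y)
  expect_error(species_permutation_pvalue(pairs4, "attr", "y"), "constant")
})

test_that("species bootstrap CI degenerates correctly and is reproducible", {
  a <- setNames(seq(0, 1, length.out = 8), sprintf("s%d", 1:8))
  D <- abs(outer(a, a, "-"))
  pairs <- make_pair_fixture(a, D) # y = x exactly, slope 1 in every resample
  ci <- species_bootstrap_ci(pairs, "attr", "y", B_boot = 50, seed = 3)
  expect_equal(ci$ci_low, 1)
  expect_equal(ci$ci_high, 1)

  set.seed(29)
  Y <- D + matrix(rnorm(64, sd = 0.1), 8)
  Y <- (Y + t(Y)) / 2
  dimnames(Y) <- dimnames(D)
  pairs2 <- make_pair_fixture(a, Y)
  c1 <- species_bootstrap_ci(pairs2, "attr", "y", B_boot = 99, seed = 11)
  c2 <- species_bootstrap_ci(pairs2, "attr", "y", B_boot = 99, seed = 11)
  expect_identical(c1$ci_low, c2$ci_low)
  expect_identical(c1$ci_high, c2$ci_high)
  expect_lte(c1$ci_low, c1$ci_high)
})

test_that("a quantreg cell reports coherent inference and tidies cleanly", {
  set.seed(31)
  a <- setNames(runif(12), sprintf("s%02d", 1:12))
  D <- abs(outer(a, a, "-"))
  Y <- 0.8 * D + matrix(rnorm(144, sd = 0.05), 12); Y <- (Y + t(Y)) / 2
  dimnames(Y) <- dimnames(D)
  pairs <- make_pair_fixture(a, Y)
  cell <- quantreg_cell(pairs, "attr", "y", B_perm = 99, B_boot = 99, seed = 1)
  expect_s3_class(cell, "fc_quantreg")
  expect_lte(cell$ci_low, cell$slope)
  expect_gte(cell$ci_high, cell$slope)
  expect_equal(cell$df, cell$n_pairs - 2L)
  expect_lte(cell$p_perm, 0.05)
  td <- tidy(cell)
  expect_equal(nrow(td), 2)
  expect_equal(td$estimate[2], cell$slope)
  gl <- glance(cell)
  expect_equal(gl$df, cell$df)
})

test_that("positive slope arises from constructed repulsion", {
  # build co-occurrence that increases with attribute distance: the sign
  # convention under which repulsion = positive slope
  a <- setNames(seq(0.2, 3, length.out = 10), sprintf("s%02d", 1:10))
  D <- abs(outer(a, a, "-"))
  Y <- 0.2 * D
  dimnames(Y) <- dimnames(D)
  pairs <- make_pair_fixture(a, Y)
  f <- quantile_fit(D[upper.tri(D)], Y[upper.tri(D)], 0.5)
  expect_gt(f$slope, 0)
})
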