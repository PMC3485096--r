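test_that("contrasts reproduce the hand-worked 3-tip example", {
  tr <- parse_newick("((A:1,B:1):1,C:2);")
  cs <- independent_contrasts(tr, c(A = 0, B = 2, C = 1))
  ab <- cs[which.min(cs$age_mean), ] # the (A,B) cherry
  expect_equal(abs(ab$contrast), 2)
  expect_equal(ab$sd, sqrt(2))
  expect_equal(abs(ab$std_contrast), 2 / sqrt(2))
  expect_equal(ab$nodal_value, 1)
  root <- cs[which.max(cs$age_mean), ]
  # adjusted internal branch 1 + 1*1/(1+1) = 1.5; root SD = sqrt(1.5 + 2)
  expect_equal(root$sd, sqrt(3.5))
  expect_equal(root$std_contrast, 0)
})

test_that("a constant trait yields all-zero contrasts", {
  tr <- random_tree(10, seed = 2)
  cs <- independent_contrasts(tr, setNames(rep(3, 10), tr$tip.label))
  expect_lt(max(abs(cs$contrast)), 1e-12)
})

test_that("standardized contrasts match ape::pic on random trees", {
  for (seed in 1:20) {
    tr <- random_tree(16, seed = 400 + seed)
    y <- simulate_brownian_trait(tr, 1, 1, seed = 500 + seed)
    ours <- independent_contrasts(tr, y)
    ref <- ape::pic(y[tr$tip.label], tr)
    expect_lt(
      max(abs(sort(abs(ours$std_contrast)) - sort(abs(ref)))),
      1e-10
    )
  }
})

test_that("sum of squared standardized contrasts equals the GLS quadratic form", {
  for (seed in 1:10) {
    tr <- random_tree(12, seed = 600 + seed)
    y <- simulate_brownian_trait(tr, 1, 1, seed = 700 + seed)
    cs <- independent_contrasts(tr, y)
    C <- ape::vcv(tr)
    yv <- y[rownames(C)]
    Ci <- solve(C)
    one <- rep(1, length(yv))
    mu <- sum(Ci %*% yv) / sum(Ci)
    q <- as.numeric(t(yv - mu) %*% Ci %*% (yv - mu))
    expect_lt(abs(sum(cs$std_contrast^2) - q), 1e-8)
  }
})

test_that("kappa transform follows its definition", {
  tr <- parse_newick("((A:1,B:2):0.5,C:3);")
  t1 <- kappa_transform(tr, 1)
  expect_equal(t1$edge.length, tr$edge.length)
  t0 <- kappa_transform(tr, 0)
  expect_true(all(t0$edge.length == 1))
  t2 <- kappa_transform(tr, 2)
  expect_setequal(t2$edge.length, c(1, 4, 0.25, 9))
  tz <- tr; tz$edge.length[1] <- 0
  expect_equal(sort(kappa_transform(tz, 0)$edge.length)[1], 0) # 0^0 := 0
  expect_error(kappa_transform(tr, -1), ">= 0")
})

test_that("optimized kappa minimises the diagnostic over its grid", {
  tr <- random_tree(24, seed = 21)
  y <- simulate_brownian_trait(tr, 1, 1, seed = 22)
  opt <- optimize_kappa(tr, y)
  expect_gte(opt$kappa, 0); expect_lte(opt$kappa, 3)
  objective <- function(k) {
    cs <- suppressWarnings(independent_contrasts(tr, y, kappa = k))
    abs(cor(cs$abs_std_contrast, cs$sd))
  }
  grid <- seq(0, 3, by = 0.05)
  expect_lte(opt$objective, min(vapply(grid, objective, numeric(1))) + 1e-9)
})

test_that("node ages and the through-origin regression behave as defined", {
  tr <- random_tree(20, seed = 25)
  y <- simulate_brownian_trait(tr, 1, 1, seed = 26)
  res <- node_age_divergence(tr, y, kappa = 1)
  # closed-form through-origin slope
  expect_equal(attr(res, "slope"),
               sum(res$age * res$abs_std_contrast) / sum(res$age^2))
  # on an ultrametric tree with kappa = 1, mean and max ages coincide
  expect_lt(max(abs(res$age_mean - res$age_max)), 1e-9)
  # root age equals tree depth
  expect_equal(max(res$age), max(ape::node.depth.edgelength(tr)))
  expect_error(node_age_divergence(parse_newick("((A:1,B:1):1,C:2);"),
                                   c(A = 1, B = 2, C = 3), kappa = 1),
               "at least 3")
})

test_that("an inflated contrast is flagged by the studentized-residual rule", {
  tr <- random_tree(31, seed = 27) # 30 internal nodes
  y <- simulate_brownian_trait(tr, 1, 1, seed = 28)
  # find a cherry and blow up its divergence
  base <- independent_contrasts(tr, y)
  cherry <- base$node[which.min(base$age_mean)]
  kids <- tr$edge[tr$edge[, 1] == cherry, 2]
  y2 <- y
  y2[tr$tip.label[kids[1]]] <- y2[tr$tip.label[kids[1]]] +
    20 * max(abs(base$contrast))
  res <- node_age_divergence(tr, y2, kappa = 1)
  expect_true(res$outlier[res$node == cherry])
  expect_lte(sum(res$outlier), 2)
  # oracle studentized residuals from the generic regression machinery
  fit <- lm(res$abs_std_contrast ~ 0 + res$age)
  expect_equal(unname(attr(res, "residuals")), unname(rstudent(fit)))
})

test_that("zero-length branches are perturbed with a warning", {
  tr <- parse_newick("((A:0,B:1):1,(C:1,D:1):1);")
  expect_warning(cs <- independent_contrasts(tr, c(A = 1, B = 2, C = 0, D = 1)),
                 "zero-length")
  expect_true(all(cs$sd > 0))
})
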