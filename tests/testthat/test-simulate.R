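test_that("Yule simulation produces ultrametric binary trees, deterministically", {
  tr <- simulate_yule_tree(16, 0.1, seed = 3)
  expect_equal(ape::Ntip(tr), 16)
  expect_true(ape::is.binary(tr))
  expect_true(ape::is.ultrametric(tr, tol = 1e-9))
  expect_identical(
    write_newick(simulate_yule_tree(16, 0.1, seed = 3)),
    write_newick(tr)
  )
  expect_error(simulate_yule_tree(2, 0.1), ">= 3")
  expect_error(simulate_yule_tree(10, 0), "> 0")
})

test_that("Yule crown depth matches the closed-form expectation", {
  # crown-conditioned pure birth: E[T] = sum_{k=2}^{n-1} 1/(bk) + 1/(bn)
  n <- 16; b <- 0.1; reps <- 300
  depths <- vapply(seq_len(reps), function(i) {
    max(ape::node.depth.edgelength(simulate_yule_tree(n, b, seed = 1000 + i)))
  }, numeric(1))
  expected <- sum(1 / (b * (2:(n - 1)))) + 1 / (b * n)
  mc_sd <- sqrt(sum(1 / (b * c(2:(n - 1), n))^2)) / sqrt(reps)
  expect_lt(abs(mean(depths) - expected), 4 * mc_sd)
})

test_that("Brownian trait simulation matches its target covariance", {
  tr <- random_tree(6, seed = 5)
  C <- ape::vcv(tr)
  reps <- 1500
  for (lam in c(0, 1)) {
    draws <- vapply(seq_len(reps), function(i) {
      simulate_brownian_trait(tr, sigma2 = 1, lambda_target = lam,
                              seed = 2000 + i)[rownames(C)]
    }, numeric(nrow(C)))
    S <- stats::cov(t(draws))
    target <- lam * C
    diag(target) <- diag(C)
    # Monte-Carlo tolerance ~ sqrt(2/reps) * scale
    expect_lt(max(abs(S - target)), 6 * max(diag(C)) * sqrt(2 / reps))
  }
  expect_identical(
    simulate_brownian_trait(tr, 1, 0.5, seed = 9),
    simulate_brownian_trait(tr, 1, 0.5, seed = 9)
  )
  expect_error(simulate_brownian_trait(tr, sigma2 = 0), "> 0")
})

test_that("binary trait simulation attains its prevalence exactly", {
  tr <- random_tree(34, seed = 8)
  s <- simulate_binary_trait(tr, 0.3, "random", seed = 1)
  expect_equal(sum(s), round(0.3 * 34))
  s2 <- simulate_binary_trait(tr, 0.3, "brownian_threshold", seed = 2)
  expect_equal(sum(s2), round(0.3 * 34))
  expect_identical(simulate_binary_trait(tr, 0.3, "random", seed = 7),
                   simulate_binary_trait(tr, 0.3, "random", seed = 7))
  expect_error(simulate_binary_trait(tr, 0.01, "random"), "degenerate")
})

test_that("the generated dataset validates and is reproducible", {
  cfg <- sim_config(n_species = 12, seed = 31)
  sim <- generate_synthetic_dataset(cfg)
  expect_s3_class(validate_survey_dataset(sim$dataset), "survey_dataset")
  expect_equal(ape::Ntip(sim$tree), 12)
  expect_equal(nrow(sim$dataset$small_abund), 24 * 4)

  sim2 <- generate_synthetic_dataset(cfg)
  expect_identical(sim$dataset$small_abund, sim2$dataset$small_abund)
  expect_identical(write_newick(sim$tree), write_newick(sim2$tree))
  expect_identical(sim$dataset$occurrences, sim2$dataset$occurrences)

  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_dataset(sim$dataset, d1); write_dataset(sim2$dataset, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
  }
})

test_that("inconsistent repulsion config is rejected", {
  cfg <- sim_config(repulsion = list(guild = "none", trait = "height",
                                     delta = 0.5, rho = 0.5))
  expect_error(generate_synthetic_dataset(cfg), "inconsistent")
  expect_error(sim_config(repulsion = list(guild = "reseeder", trait = "height",
                                           delta = 0.5, rho = 1.5)), "rho")
  expect_error(sim_config(birth_rate = -1), "birth_rate")
})

test_that("repulsion suppresses co-occurrence of similar same-guild pairs", {
  base <- list(guild = "reseeder", trait = "height", delta = 0.8, rho = 0.95)
  sim_on <- generate_synthetic_dataset(sim_config(n_species = 20, seed = 77,
                                                  repulsion = base))
  off <- base; off$rho <- 0
  sim_off <- generate_synthetic_dataset(sim_config(n_species = 20, seed = 77,
                                                   repulsion = off))
  # same latent world (same seed), repulsion only removes individuals
  on_m <- as.matrix(sim_on$dataset$small_abund[-1])
  off_m <- as.matrix(sim_off$dataset$small_abund[-1])
  expect_true(all(on_m <= off_m))
  expect_lt(sum(on_m), sum(off_m))
})
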