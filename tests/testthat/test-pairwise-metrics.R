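test_that("Schoener's index matches the direct formula", {
  a <- cbind(sp1 = c(2, 2, 0), sp2 = c(0, 2, 2))
  expect_equal(schoener_cij(a)["sp1", "sp2"], 0.5)
  b <- cbind(x = c(1, 2, 3), y = c(2, 4, 6))      # identical profiles
  expect_equal(schoener_cij(b)["x", "y"], 1)
  d <- cbind(x = c(5, 0), y = c(0, 3))            # disjoint profiles
  expect_equal(schoener_cij(d)["x", "y"], 0)
  expect_error(schoener_cij(cbind(x = c(1, 1), z = c(0, 0))), "z")
})

test_that("Schoener's index agrees with picante and is scale/order invariant", {
  set.seed(3)
  m <- matrix(rpois(8 * 6, 3), 8, 6, dimnames = list(NULL, paste0("s", 1:6)))
  m[, 3] <- m[, 3] + 1 # guard against zero totals
  ours <- schoener_cij(m)
  pic <- as.matrix(picante::species.dist(m, metric = "cij"))
  pic <- pic[colnames(m), colnames(m)]
  diag(pic) <- 1
  expect_lt(max(abs(ours - pic)), 1e-12)
  # plot order must not matter
  expect_equal(schoener_cij(m[sample(8), ]), ours)
  # per-species rescaling must not matter (row normalization)
  m2 <- m; m2[, 2] <- m2[, 2] * 7
  expect_lt(max(abs(schoener_cij(m2) - ours)), 1e-12)
})

test_that("flowering overlap dissimilarity follows its formula", {
  expect_equal(flowering_overlap_dissim(1:3, 2:4), 1 - 2 / 3)
  expect_equal(flowering_overlap_dissim(c(11, 12, 1, 2), c(1, 2)), 0)
  expect_equal(flowering_overlap_dissim(1, 7), 1)
  expect_equal(flowering_overlap_dissim(3:5, 3:5), 0)
  expect_error(flowering_overlap_dissim(integer(0), 1:2), "nonempty")
  expect_error(flowering_overlap_dissim(1:2, 13), "1..12")
})

test_that("edaphic preference slopes equal the OLS oracle", {
  # log(n+1) = (0, 1, 2) against x = (0, 1, 2) -> slope exactly 1
  ab <- cbind(spX = exp(0:2) - 1, spY = c(2, 2, 2))
  soil <- cbind(nitrate = c(0, 1, 2))
  sl <- edaphic_preference_slopes(ab, soil)
  expect_equal(sl$nitrate[sl$species == "spX"], 1)
  expect_equal(sl$nitrate[sl$species == "spY"], 0) # constant abundance

  set.seed(5)
  ab2 <- matrix(rpois(96 * 5, 4), 96, 5, dimnames = list(NULL, paste0("s", 1:5)))
  soil2 <- matrix(rnorm(96 * 2), 96, 2, dimnames = list(NULL, c("ph", "calcium")))
  sl2 <- edaphic_preference_slopes(ab2, soil2)
  for (v in c("ph", "calcium")) {
    for (s in 1:5) {
      oracle <- unname(coef(lm(log(ab2[, s] + 1) ~ soil2[, v]))[2])
      expect_lt(abs(sl2[[v]][s] - oracle), 1e-10)
    }
  }
  expect_error(
    edaphic_preference_slopes(ab2, cbind(ph = rep(1, 96))), "constant"
  )
})

test_that("the pair table covers all pairs with correct distances and guilds", {
  cfg <- sim_config(n_species = 5, seed = 13)
  sim <- generate_synthetic_dataset(cfg)
  pairs <- suppressMessages(build_pair_table(sim$dataset, sim$tree))
  expect_equal(nrow(pairs), choose(5, 2))
  expect_true(all(is.finite(pairs$phylo_dist)))

  tr <- sim$dataset$traits
  h <- setNames(tr$height_m, tr$species)
  expect_equal(pairs$d_height,
               abs(h[pairs$species_a] - h[pairs$species_b]),
               ignore_attr = TRUE)
  pd <- patristic_distances(sim$tree)
  expect_equal(pairs$phylo_dist, pd[cbind(pairs$species_a, pairs$species_b)],
               ignore_attr = TRUE)
  g <- setNames(tr$regen_mode, tr$species)
  both_res <- g[pairs$species_a] == "reseeder" & g[pairs$species_b] == "reseeder"
  expect_equal(pairs$guild_combo == "reseeder_reseeder", unname(both_res))

  # distances are symmetric dissimilarities: identical species-level values
  # give zero distance
  sl <- edaphic_preference_slopes(sim$dataset)
  for (v in fc_soil_vars) {
    expect_equal(pairs[[paste0("d_soil_", v)]],
                 abs(sl[[v]][match(pairs$species_a, sl$species)] -
                     sl[[v]][match(pairs$species_b, sl$species)]),
                 ignore_attr = TRUE)
  }
})

test_that("species missing from the tree keep trait distances, flagged phylo", {
  cfg <- sim_config(n_species = 6, seed = 14)
  sim <- generate_synthetic_dataset(cfg)
  pruned <- ape::drop.tip(sim$tree, "sp01")
  pairs <- suppressMessages(build_pair_table(sim$dataset, pruned))
  expect_equal(nrow(pairs), choose(6, 2))
  off <- pairs$species_a == "sp01" | pairs$species_b == "sp01"
  expect_true(all(is.na(pairs$phylo_dist[off])))
  expect_true(all(is.finite(pairs$phylo_dist[!off])))
  expect_true(all(is.finite(pairs$d_height)))
})

test_that("patristic distance of sister tips is the sum of their branches", {
  tr <- parse_newick("((A:1,B:1):1,C:2);")
  ds <- tiny_dataset()
  # rename species to match the tree
  names(ds$small_abund) <- c("plot_id", "A", "B", "C")
  ds$traits$species <- c("A", "B", "C")
  ds$large_presence <- NULL
  ds2 <- survey_dataset(ds$small_abund, ds$soil, ds$traits,
                        ds$occurrences |> dplyr::mutate(species = rep(c("A", "B", "C"), each = 4)))
  pairs <- suppressMessages(build_pair_table(ds2, tr))
  expect_equal(pairs$phylo_dist[pairs$species_a == "A" & pairs$species_b == "B"], 2)
})

test_that("the retained mask filters pairs and rejects unknown species", {
  cfg <- sim_config(n_species = 5, seed = 15)
  sim <- generate_synthetic_dataset(cfg)
  mask <- tibble::tibble(species_a = "sp01", species_b = "sp02", retained = FALSE)
  pairs <- suppressMessages(build_pair_table(sim$dataset, sim$tree, mask))
  expect_equal(nrow(pairs), choose(5, 2) - 1)
  bad <- tibble::tibble(species_a = "ghost", species_b = "sp02", retained = TRUE)
  expect_error(suppressMessages(build_pair_table(sim$dataset, sim$tree, bad)),
               "unknown species")
})
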