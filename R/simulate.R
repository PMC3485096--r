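#' Configuration for the synthetic survey generator
#'
#' Collects every knob of the synthetic world in one validated list. The
#' defaults emulate the survey design the analysis targets: 24 large plots
#' each containing 4 subplots, ~39 shrub species in two fire-response
#' guilds, soil gradients across the region, phylogenetically conserved
#' height and seed size (lambda = 1 Brownian on the log scale), labile
#' flowering schedules and labile edaphic preferences (i.i.d. slopes), and
#' an optional guild-specific co-occurrence repulsion mechanism.
#'
#' @param n_species Number of species (>= 3).
#' @param birth_rate Yule speciation rate per Myr; the default 0.08 puts
#'   the expected crown depth of a 39-tip tree near 40 Myr.
#' @param trait_sigma2 Named vector: Brownian rate per Myr for `height`
#'   and `seed` on the log scale.
#' @param lambda_target Named vector in `[0, 1]`: phylogenetic signal of
#'   the generated log-height and log-seed values.
#' @param guild_prevalence Proportion of species in the reseeder guild.
#' @param guild_mode `"random"` (labile regeneration mode) or
#'   `"brownian_threshold"` (conserved).
#' @param n_large_plots,n_subplots Plot design (subplots per large plot).
#' @param soil_gradient_params Tibble with columns `variable`, `mean`,
#'   `sd` (subplot noise), `trend` (total change across the large-plot
#'   sequence, emulating a regional gradient).
#' @param pref_slope_sd Named vector of SDs for the i.i.d. per-species
#'   edaphic response slopes (per unit of each soil variable); `NULL`
#'   scales 0.6 log-units per SD of each soil variable.
#' @param base_log_abund Mean and SD of species' baseline log intensity.
#' @param repulsion List with `guild` (`"reseeder"`, `"resprouter"` or
#'   `"none"`), `trait` (`"height"` or `"phylo"`), `delta` (similarity
#'   threshold: metres for height, Myr for patristic distance) and `rho`
#'   (per-subplot exclusion probability in `[0, 1]`).
#' @param presence_extra Probability that a species absent from all four
#'   subplots is nonetheless recorded as present at the large-plot scale
#'   (it was seen outside the subplots).
#' @param range_radius_mean,range_radius_sd Circular range radius (deg).
#' @param n_records_per_species Occurrence records per species.
#' @param study_box Bounding box `c(lon_min, lon_max, lat_min, lat_max)`.
#' @param seed Master seed; every internal stream is derived from it.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_species = 39,
                       birth_rate = 0.08,
                       trait_sigma2 = c(height = 0.02, seed = 0.02),
                       lambda_target = c(height = 1, seed = 1),
                       guild_prevalence = 0.6,
                       guild_mode = c("random", "brownian_threshold"),
                       n_large_plots = 24,
                       n_subplots = 4,
                       soil_gradient_params = default_soil_params(),
                       pref_slope_sd = NULL,
                       base_log_abund = c(mean = log(3), sd = 0.4),
                       repulsion = list(guild = "none", trait = "height",
                                        delta = 0.5, rho = 0),
                       presence_extra = 0.02,
                       range_radius_mean = 1.0,
                       range_radius_sd = 0.3,
                       n_records_per_species = 30,
                       study_box = c(115, 118, -35, -32),
                       seed = NULL) {
  guild_mode <- match.arg(guild_mode)
  if (n_species < 3) abort("`n_species` must be >= 3.")
  if (birth_rate <= 0) abort("`birth_rate` must be > 0.")
  if (any(trait_sigma2 <= 0)) abort("`trait_sigma2` entries must be > 0.")
  if (any(lambda_target < 0 | lambda_target > 1)) abort("`lambda_target` must lie in [0, 1].")
  if (guild_prevalence <= 0 || guild_prevalence >= 1) abort("`guild_prevalence` must be in (0, 1).")
  if (!repulsion$guild %in% c("reseeder", "resprouter", "none")) {
    abort("repulsion$guild must be 'reseeder', 'resprouter' or 'none'.")
  }
  if (!repulsion$trait %in% c("height", "phylo")) {
    abort("repulsion$trait must be 'height' or 'phylo'.")
  }
  if (repulsion$rho < 0 || repulsion$rho > 1) abort("repulsion$rho must be in [0, 1].")
  sg <- as_tibble(soil_gradient_params)
  if (!setequal(sg$variable, fc_soil_vars)) {
    abort("soil_gradient_params must cover exactly the seven soil variables.")
  }
  if (is.null(pref_slope_sd)) {
    spread <- sqrt(sg$sd^2 + sg$trend^2 / 12)
    pref_slope_sd <- setNames(0.6 / spread, sg$variable)
  }
  structure(
    list(
      n_species = as.integer(n_species), birth_rate = birth_rate,
      trait_sigma2 = trait_sigma2, lambda_target = lambda_target,
      guild_prevalence = guild_prevalence, guild_mode = guild_mode,
      n_large_plots = as.integer(n_large_plots),
      n_subplots = as.integer(n_subplots),
      soil_gradient_params = sg, pref_slope_sd = pref_slope_sd,
      base_log_abund = base_log_abund, repulsion = repulsion,
      presence_extra = presence_extra,
      range_radius_mean = range_radius_mean,
      range_radius_sd = range_radius_sd,
      n_records_per_species = as.integer(n_records_per_species),
      study_box = study_box, seed = seed
    ),
    class = "sim_config"
  )
}

#' @rdname sim_config
#' @export
default_soil_params <- function() {
  tibble(
    variable = fc_soil_vars,
    mean = c(300, 40, 5, 2, 5.5, 2.5, 20),
    sd = c(60, 8, 1, 0.5, 0.3, 0.6, 5),
    trend = c(150, -15, 2, 1.2, 0.8, -1, 8)
  )
}

#' Simulate a Yule (pure-birth) tree
#'
#' Crown-conditioned pure-birth simulation: two lineages at the crown,
#' waiting time between the k-th and (k+1)-lineage stage exponential with
#' rate `k * birth_rate`, a uniformly chosen lineage splitting at each
#' event, and a final exponential stretch with rate `n * birth_rate`
#' before the present. The result is an ultrametric binary tree with `n`
#' tips labelled `sp01 ... spNN`.
#'
#' @param n Number of tips (>= 3).
#' @param birth_rate Speciation rate per Myr.
#' @param seed RNG seed.
#' @return A `phylo`.
#' @export
simulate_yule_tree <- function(n, birth_rate = 0.08, seed = NULL) {
  if (n < 3) abort("`n` must be >= 3.")
  if (birth_rate <= 0) abort("`birth_rate` must be > 0.")
  with_seed(seed, {
    total <- 2L * n - 1L
    parent <- integer(total)
    btime <- numeric(total)
    is_tip <- rep(TRUE, total)
    etime <- numeric(total)

    # node 1 = root (crown) at time 0 with children 2 and 3
    is_tip[1] <- FALSE
    parent[2:3] <- 1L
    active <- c(2L, 3L)
    nxt <- 4L
    t_now <- 0

    while (length(active) < n) {
      k <- length(active)
      t_now <- t_now + rexp(1, rate = k * birth_rate)
      i <- active[sample.int(k, 1)]
      is_tip[i] <- FALSE
      etime[i] <- t_now
      kids <- c(nxt, nxt + 1L)
      parent[kids] <- i
      btime[kids] <- t_now
      active <- c(setdiff(active, i), kids)
      nxt <- nxt + 2L
    }
    t_now <- t_now + rexp(1, rate = n * birth_rate)
    etime[active] <- t_now

    tips <- which(is_tip)
    internals <- which(!is_tip)
    newid <- integer(total)
    newid[tips] <- seq_len(n)
    newid[internals] <- n + seq_along(internals) # root (node 1) -> n+1

    nonroot <- setdiff(seq_len(total), 1L)
    edge <- cbind(newid[parent[nonroot]], newid[nonroot])
    edge.length <- etime[nonroot] - btime[nonroot]
    tree <- list(
      edge = edge,
      edge.length = edge.length,
      tip.label = sprintf("sp%02d", seq_len(n)),
      Nnode = n - 1L
    )
    class(tree) <- "phylo"
    ape::reorder.phylo(tree, "cladewise")
  })
}

#' Simulate a Brownian trait with target lambda
#'
#' Draws tip values from a multivariate normal with covariance
#' `sigma2 * C(lambda)`: the Brownian covariance of shared path lengths
#' with off-diagonals multiplied by `lambda_target`. `lambda = 1` is plain
#' Brownian motion; `lambda = 0` gives i.i.d. values with the Brownian tip
#' variances.
#'
#' @param tree A `phylo`.
#' @param sigma2 Brownian rate (> 0) per unit branch length.
#' @param lambda_target Signal strength in `[0, 1]`.
#' @param root Root (mean) value added to every tip.
#' @param seed RNG seed.
#' @return Named numeric vector of tip values.
#' @export
simulate_brownian_trait <- function(tree, sigma2 = 1, lambda_target = 1,
                                    root = 0, seed = NULL) {
  if (sigma2 <= 0) abort("`sigma2` must be > 0.")
  if (lambda_target < 0 || lambda_target > 1) abort("`lambda_target` must be in [0, 1].")
  tree <- validate_phylogeny(tree)
  V <- sigma2 * lambda_vcv_target(tree, lambda_target)
  with_seed(seed, {
    L <- t(chol(V))
    x <- root + as.vector(L %*% rnorm(nrow(V)))
    setNames(x, rownames(V))
  })
}

lambda_vcv_target <- function(tree, lam) {
  C <- ape::vcv(tree)
  V <- lam * C
  diag(V) <- diag(C)
  V
}

#' Simulate a binary trait with fixed prevalence
#'
#' `mode = "brownian_threshold"` thresholds a Brownian (lambda = 1)
#' liability at its empirical quantile so that exactly
#' `round(prevalence * n)` tips carry state 1 (conserved trait with no
#' prevalence drift); `mode = "random"` places the same number of 1s
#' uniformly at random (labile trait).
#'
#' @param tree A `phylo`.
#' @param prevalence Target proportion of state-1 tips; both states must
#'   end up with at least 2 tips.
#' @param mode `"brownian_threshold"` or `"random"`.
#' @param seed RNG seed.
#' @return Named 0/1 vector per tip.
#' @export
simulate_binary_trait <- function(tree, prevalence,
                                  mode = c("random", "brownian_threshold"),
                                  seed = NULL) {
  mode <- match.arg(mode)
  tree <- validate_phylogeny(tree)
  n <- ape::Ntip(tree)
  k <- round(prevalence * n)
  if (k < 2 || n - k < 2) {
    abort("degenerate prevalence: each state needs at least 2 tips.")
  }
  with_seed(seed, {
    s <- setNames(rep(0, n), tree$tip.label)
    if (mode == "random") {
      s[sample.int(n, k)] <- 1
    } else {
      liab <- simulate_brownian_trait(tree, sigma2 = 1, lambda_target = 1)
      thr <- sort(liab, decreasing = TRUE)[k]
      s[names(liab)[liab >= thr]] <- 1
    }
    s
  })
}

#' Generate a complete synthetic survey dataset
#'
#' Assembles the full synthetic world from a [sim_config()]: a dated Yule
#' tree; conserved log-height and log-seed traits; labile flowering
#' schedules; a two-guild regeneration mode; soil variables following a
#' regional linear gradient across the large-plot sequence plus subplot
#' noise; per-species edaphic response slopes drawn i.i.d. (labile by
#' construction); Poisson counts with log intensity linear in the centred
#' soil variables; an optional repulsion stage that, within each subplot
#' and for each same-guild pair closer than `delta` in the chosen trait,
#' zeroes the rarer member's count with probability `rho` (ecological
#' sorting, not evolution); and circular geographic ranges with uniform
#' occurrence records. Every latent quantity is stored in the `truth`
#' record for recovery tests.
#'
#' @param cfg A `sim_config`.
#' @return List with `dataset` (validated `survey_dataset`), `tree`
#'   (`phylo`) and `truth` (list of latent parameters).
#' @export
generate_synthetic_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  rep_cfg <- cfg$repulsion
  if (rep_cfg$guild == "none" && rep_cfg$rho > 0) {
    abort("inconsistent config: repulsion rho > 0 with guild = 'none'.")
  }
  seed <- cfg$seed
  tree <- simulate_yule_tree(cfg$n_species, cfg$birth_rate, seed = child_seed(seed, "tree"))
  sp <- tree$tip.label
  n <- length(sp)

  log_height <- simulate_brownian_trait(
    tree, cfg$trait_sigma2[["height"]], cfg$lambda_target[["height"]],
    root = log(1.5), seed = child_seed(seed, "height")
  )
  log_seed <- simulate_brownian_trait(
    tree, cfg$trait_sigma2[["seed"]], cfg$lambda_target[["seed"]],
    root = log(5), seed = child_seed(seed, "seed")
  )
  height <- pmax(exp(log_height), 0.2)
  seed_mm <- pmax(exp(log_seed), 0.5)

  guild01 <- simulate_binary_trait(
    tree, cfg$guild_prevalence, cfg$guild_mode, seed = child_seed(seed, "guild")
  )
  guild <- ifelse(guild01 == 1, "reseeder", "resprouter")

  flowering <- with_seed(child_seed(seed, "flowering"), {
    lapply(seq_len(n), function(i) {
      start <- sample.int(12, 1)
      len <- sample(2:6, 1)
      sort(((start - 1 + seq_len(len) - 1) %% 12) + 1)
    })
  })

  L <- cfg$n_large_plots
  K <- cfg$n_subplots
  sg <- cfg$soil_gradient_params
  soil <- with_seed(child_seed(seed, "soil"), {
    vals <- sapply(seq_len(nrow(sg)), function(v) {
      lp <- rep(seq_len(L), each = K)
      sg$mean[v] + sg$trend[v] * (lp - (L + 1) / 2) / L + rnorm(L * K, 0, sg$sd[v])
    })
    colnames(vals) <- sg$variable
    vals
  })
  plot_ids <- paste0(sprintf("L%02d", rep(seq_len(L), each = K)), "_S", rep(seq_len(K), L))

  beta <- with_seed(child_seed(seed, "slopes"), {
    b <- sapply(sg$variable, function(v) rnorm(n, 0, cfg$pref_slope_sd[[v]]))
    rownames(b) <- sp
    b
  })
  base <- with_seed(child_seed(seed, "base"), {
    setNames(rnorm(n, cfg$base_log_abund[["mean"]], cfg$base_log_abund[["sd"]]), sp)
  })

  soil_c <- sweep(soil, 2, sg$mean[match(colnames(soil), sg$variable)], "-")
  eta <- sweep(soil_c %*% t(beta), 2, base, "+") # plots x species
  eta <- pmin(pmax(eta, -6), 4)
  counts <- with_seed(child_seed(seed, "counts"), {
    m <- matrix(rpois(length(eta), exp(eta)), nrow(eta), ncol(eta))
    dimnames(m) <- list(plot_ids, sp)
    m
  })

  if (rep_cfg$guild != "none" && rep_cfg$rho > 0) {
    if (rep_cfg$trait == "height") {
      D <- abs(outer(height, height, "-"))
    } else {
      D <- patristic_distances(tree)[sp, sp]
    }
    in_guild <- sp[guild == rep_cfg$guild]
    pair_idx <- which(
      upper.tri(D) & D < rep_cfg$delta &
        outer(sp %in% in_guild, sp %in% in_guild, "&"),
      arr.ind = TRUE
    )
    counts <- with_seed(child_seed(seed, "repulsion"), {
      for (r in seq_len(nrow(pair_idx))) {
        i <- pair_idx[r, 1]; j <- pair_idx[r, 2]
        both <- counts[, i] > 0 & counts[, j] > 0
        if (!any(both)) next
        hit <- both & runif(nrow(counts)) < rep_cfg$rho
        if (!any(hit)) next
        loser_j <- counts[hit, j] <= counts[hit, i]
        rows <- which(hit)
        counts[rows[loser_j], j] <- 0L
        counts[rows[!loser_j], i] <- 0L
      }
      counts
    })
  }

  presence <- rowsum(counts, group = rep(seq_len(L), each = K)) > 0
  presence <- with_seed(child_seed(seed, "presence"), {
    somewhere <- colSums(counts) > 0
    extra <- matrix(runif(length(presence)) < cfg$presence_extra, nrow(presence))
    presence | sweep(extra, 2, somewhere, "&")
  })
  rownames(presence) <- sprintf("L%02d", seq_len(L))

  occ <- with_seed(child_seed(seed, "ranges"), {
    box <- cfg$study_box
    centers <- cbind(
      runif(n, box[1], box[2]),
      runif(n, box[3], box[4])
    )
    radius <- pmax(abs(rnorm(n, cfg$range_radius_mean, cfg$range_radius_sd)), 0.05)
    recs <- lapply(seq_len(n), function(i) {
      u <- runif(cfg$n_records_per_species)
      th <- runif(cfg$n_records_per_species, 0, 2 * pi)
      r <- radius[i] * sqrt(u)
      tibble(
        species = sp[i],
        lon = centers[i, 1] + r * cos(th),
        lat = centers[i, 2] + r * sin(th)
      )
    })
    list(records = bind_rows(recs), centers = centers, radius = radius)
  })

  ds <- survey_dataset(
    small_abund = tibble(plot_id = plot_ids) |>
      dplyr::bind_cols(as_tibble(as.data.frame(counts))),
    soil = tibble(plot_id = plot_ids) |>
      dplyr::bind_cols(as_tibble(as.data.frame(soil))),
    traits = tibble(
      species = sp, height_m = unname(height[sp]), seed_mm = unname(seed_mm[sp]),
      regen_mode = unname(guild[sp]), flowering = flowering
    ),
    occurrences = occ$records,
    large_presence = tibble(large_plot = rownames(presence)) |>
      dplyr::bind_cols(as_tibble(as.data.frame(presence)))
  )

  truth <- list(
    config = cfg,
    log_height = log_height, log_seed = log_seed,
    guild = guild, flowering = flowering,
    soil_means = sg$mean, beta = beta, base = base,
    range_centers = occ$centers, range_radius = occ$radius
  )
  list(dataset = ds, tree = tree, truth = truth)
}
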