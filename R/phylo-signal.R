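# Lambda-scaled phylogenetic covariance: off-diagonal (shared-path)
# entries multiplied by lambda, tip variances (root-to-tip depths)
# unchanged.
lambda_vcv <- function(tree, lam) {
  C <- ape::vcv(tree)
  V <- lam * C
  diag(V) <- diag(C)
  V
}

#' Log-likelihood of a trait under the lambda model
#'
#' Profile log-likelihood of Pagel's lambda: the trait is modelled as
#' multivariate normal with mean `mu * 1` and covariance
#' `sigma2 * C(lambda)`, where `C(lambda)` keeps the tip variances of the
#' Brownian covariance and multiplies the shared-path off-diagonals by
#' `lambda`. `mu` and `sigma2` are profiled out analytically by GLS, so
#' the returned value is the log-likelihood maximised over both.
#'
#' @param tree Rooted binary `phylo` (>= 3 tips).
#' @param trait Named numeric tip vector (non-constant).
#' @param lam Lambda in `[0, 1]`.
#' @return List with `loglik`, `mu`, `sigma2`.
#' @export
lambda_loglik <- function(tree, trait, lam) {
  tree <- validate_phylogeny(tree)
  y <- align_trait(tree, trait)
  lambda_loglik_C(ape::vcv(tree)[names(y), names(y)], y, lam)
}

# workhorse on a precomputed Brownian covariance (avoids rebuilding C at
# every point of the likelihood profile)
lambda_loglik_C <- function(C, y, lam) {
  if (!is.numeric(lam) || length(lam) != 1L || lam < 0 || lam > 1) {
    abort("`lam` must be a single value in [0, 1].")
  }
  if (stats::sd(y) == 0) abort("trait is constant; lambda is undefined.")
  n <- length(y)
  V <- lam * C
  diag(V) <- diag(C)
  R <- tryCatch(chol(V), error = function(e) abort("singular lambda covariance matrix."))
  logdet <- 2 * sum(log(diag(R)))
  solve_chol <- function(v) backsolve(R, backsolve(R, v, transpose = TRUE))
  Vi1 <- solve_chol(rep(1, n))
  mu <- sum(Vi1 * y) / sum(Vi1)
  r <- y - mu
  q <- sum(r * solve_chol(r))
  sigma2 <- q / n
  ll <- -n / 2 * log(2 * pi * sigma2) - logdet / 2 - n / 2
  list(loglik = ll, mu = mu, sigma2 = sigma2)
}

align_trait <- function(tree, trait) {
  if (is.null(names(trait))) abort("trait values must be named by tip label.")
  miss <- setdiff(tree$tip.label, names(trait))
  if (length(miss) > 0) {
    abort(paste0("trait values missing for tips: ", paste(miss, collapse = ", ")))
  }
  v <- trait[tree$tip.label]
  if (anyNA(v)) abort("trait contains NA for tree tips.")
  v
}

#' Maximum-likelihood estimate of Pagel's lambda
#'
#' Maximises [lambda_loglik()] over `[0, 1]` (101-point grid pre-scan then
#' bounded 1-D optimization, tolerance 1e-6) and tests the estimate
#' against lambda = 0 (no signal: "labile") and lambda = 1 (Brownian) by
#' likelihood-ratio statistics referred to a 50:50 mixture of chi-square(0)
#' and chi-square(1) — the boundary-respecting null for a parameter
#' constrained to `[0, 1]`.
#'
#' @inheritParams lambda_loglik
#' @param trait_name Label carried into the result.
#' @return An `fc_lambda` object: `lambda_ml`, `loglik_ml`, `loglik0`,
#'   `loglik1`, `p_labile`, `p_brownian`, `sigma2_ml`, `mean_ml`.
#' @export
pagel_lambda_ml <- function(tree, trait, trait_name = NULL) {
  tree <- validate_phylogeny(tree)
  y <- align_trait(tree, trait)
  C <- ape::vcv(tree)[names(y), names(y)]
  f <- function(l) lambda_loglik_C(C, y, l)$loglik
  grid <- seq(0, 1, length.out = 101)
  vals <- vapply(grid, f, numeric(1))
  i <- which.max(vals)
  lo <- grid[max(1L, i - 1L)]
  hi <- grid[min(length(grid), i + 1L)]
  op <- optimize(f, c(lo, hi), maximum = TRUE, tol = 1e-6)
  cand <- rbind(
    c(op$maximum, op$objective),
    c(grid[i], vals[i]),
    c(0, vals[1]),
    c(1, vals[length(vals)])
  )
  best <- cand[which.max(cand[, 2]), ]
  fit <- lambda_loglik_C(C, y, best[1])
  lr_p <- function(ll0) {
    lr <- 2 * (best[2] - ll0)
    if (lr <= 1e-10) 1 else 0.5 * pchisq(lr, df = 1, lower.tail = FALSE)
  }
  structure(
    list(
      trait = trait_name %||% "trait",
      lambda_ml = unname(best[1]),
      loglik_ml = unname(best[2]),
      loglik0 = vals[1],
      loglik1 = vals[length(vals)],
      p_labile = lr_p(vals[1]),
      p_brownian = lr_p(vals[length(vals)]),
      sigma2_ml = fit$sigma2,
      mean_ml = fit$mu
    ),
    class = "fc_lambda"
  )
}

#' @export
print.fc_lambda <- function(x, ...) {
  cat(sprintf(
    "Pagel's lambda [%s]: lambda = %.4g  p(labile) = %.4g  p(Brownian) = %.4g\n",
    x$trait, x$lambda_ml, x$p_labile, x$p_brownian
  ))
  invisible(x)
}

# Sum over internal nodes of |sister-clade difference in nodal estimates|,
# where nodal estimates come from the Felsenstein averaging pass applied
# to the 0/1 states. Vectorised over columns of a state matrix.
d_sum_of_changes <- function(tree, states) {
  pp <- prune_pass(tree, states)
  colSums(abs(pp$contrasts))
}

#' D statistic for phylogenetic signal in a binary trait
#'
#' The observed sum of sister-clade differences in nodal estimates of the
#' 0/1 trait (Felsenstein averaging pass) is scaled between the means of
#' two simulated nulls at the observed prevalence:
#' `D = (d_obs - mean d_Brownian) / (mean d_random - mean d_Brownian)`.
#' D is about 1 when states are phylogenetically random and about 0 when
#' they arise from thresholding a Brownian liability. `p_random` is the
#' fraction of random-shuffle draws with `d <= d_obs` (small = clumped,
#' i.e. signal); `p_brownian` is the fraction of threshold-Brownian draws
#' with `d >= d_obs` (small = overdispersed relative to Brownian).
#'
#' @param tree Rooted binary `phylo`.
#' @param states Named 0/1 vector per tip; both states need >= 2 tips.
#' @param n_sims Draws per null (default 1000).
#' @param seed RNG seed.
#' @return An `fc_dstat` object: `d_obs`, `D`, `p_random`, `p_brownian`,
#'   `n_sims`, `undefined` flag.
#' @export
d_statistic <- function(tree, states, n_sims = 1000, seed = NULL) {
  tree <- validate_phylogeny(tree)
  s <- align_trait(tree, states)
  if (!all(s %in% c(0, 1))) abort("states must be 0/1.")
  k <- sum(s == 1)
  n <- length(s)
  if (k < 2 || n - k < 2) {
    abort("both states must be present on at least 2 tips each.")
  }
  d_obs <- d_sum_of_changes(tree, s)

  with_seed(seed, {
    shuf <- matrix(0, n, n_sims, dimnames = list(names(s), NULL))
    for (b in seq_len(n_sims)) shuf[sample.int(n, k), b] <- 1
    d_rand <- d_sum_of_changes(tree, shuf)

    C <- ape::vcv(tree)[names(s), names(s)]
    L <- t(chol(C))
    z <- L %*% matrix(rnorm(n * n_sims), n)
    thr <- apply(z, 2, function(col) sort(col, decreasing = TRUE)[k])
    bs <- (sweep(z, 2, thr, "-") >= 0) * 1
    rownames(bs) <- names(s)
    d_brown <- d_sum_of_changes(tree, bs)

    denom <- mean(d_rand) - mean(d_brown)
    undefined <- abs(denom) < 1e-12
    structure(
      list(
        d_obs = unname(d_obs),
        D = if (undefined) NA_real_ else unname((d_obs - mean(d_brown)) / denom),
        p_random = mean(d_rand <= d_obs),
        p_brownian = mean(d_brown >= d_obs),
        n_sims = n_sims,
        undefined = undefined
      ),
      class = "fc_dstat"
    )
  })
}

#' @export
print.fc_dstat <- function(x, ...) {
  cat(sprintf(
    "D statistic: D = %.4g (d_obs = %.4g)  p(random) = %.4g  p(Brownian) = %.4g  [%d sims/null]\n",
    x$D, x$d_obs, x$p_random, x$p_brownian, x$n_sims
  ))
  invisible(x)
}

#' Phylogenetic signal in flowering-period overlap
#'
#' Flowering schedules are pairwise data (overlap between two species), so
#' their signal is assessed as a quantile regression of the
#' flowering-overlap dissimilarity on patristic distance across species
#' pairs, with the same species-permutation inference as the co-occurrence
#' analyses. A positive slope means more distantly related species flower
#' at more dissimilar times.
#'
#' @inheritParams quantreg_cell
#' @return An `fc_quantreg` object.
#' @export
flowering_overlap_signal <- function(pairs, tau = 0.5, B_perm = 199,
                                     B_boot = 199, seed = NULL) {
  if (all(!is.finite(pairs$phylo_dist))) {
    abort("pair table has no patristic distances; supply a tree to build_pair_table().")
  }
  quantreg_cell(
    pairs, predictor = "phylo", response = "flower_overlap",
    subset = "all", tau = tau, B_perm = B_perm, B_boot = B_boot, seed = seed
  )
}

#' Summarise a signal statistic across a sample of trees
#'
#' Applies a per-tree statistic (e.g. [pagel_lambda_ml()] or
#' [d_statistic()]) to each tree in a posterior sample and reports the
#' median and 2.5/97.5 percentiles of every numeric component, the
#' convention for reporting statistics over a Bayesian tree sample.
#'
#' @param trees A list of `phylo` objects (or a `multiPhylo`).
#' @param fn Function of a single tree returning an object with numeric
#'   components (or a named numeric vector).
#' @param ... Passed to `fn`.
#' @return List with `per_tree` (tibble, one row per tree) and `summary`
#'   (tibble with statistic, median, q025, q975).
#' @export
signal_across_trees <- function(trees, fn, ...) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  rows <- purrr::map(seq_along(trees), function(i) {
    res <- fn(trees[[i]], ...)
    if (!is.list(res)) res <- as.list(res)
    num <- res[vapply(res, function(v) is.numeric(v) && length(v) == 1L, logical(1))]
    tibble(tree = i) |> dplyr::bind_cols(as_tibble(num))
  })
  per_tree <- bind_rows(rows)
  stats_cols <- setdiff(names(per_tree), "tree")
  summary <- purrr::map_dfr(stats_cols, function(cl) {
    v <- per_tree[[cl]]
    tibble(
      statistic = cl,
      median = median(v, na.rm = TRUE),
      q025 = unname(quantile(v, 0.025, na.rm = TRUE, type = 7)),
      q975 = unname(quantile(v, 0.975, na.rm = TRUE, type = 7))
    )
  })
  list(per_tree = per_tree, summary = summary)
}
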