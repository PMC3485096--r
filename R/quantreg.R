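#' Check-function loss of quantile regression
#'
#' `rho_tau(r) = r * (tau - 1[r < 0])`, the asymmetric absolute loss whose
#' minimiser is the tau-th conditional quantile.
#'
#' @param r Residual vector.
#' @param tau Quantile level in (0, 1).
#' @return Vector of losses.
#' @export
rho_tau <- function(r, tau) r * (tau - (r < 0))

# Optimal intercept for fixed slope b: the tau-th order statistic of the
# residuals y - b x (any point of the minimising interval works; we take
# the lower endpoint).
tau_intercept <- function(r, tau) {
  n <- length(r)
  k <- ceiling(tau * n)
  k <- min(max(k, 1L), n)
  sort(r, partial = k)[k]
}

# Subgradient interval of the profiled objective G(b) = min_a R(a, b).
# Returns c(lo, hi); G is convex piecewise linear so the interval is exact
# up to the zero-residual tolerance.
profile_subgradient <- function(x, y, b, tau) {
  r <- y - b * x
  a <- tau_intercept(r, tau)
  e <- r - a
  tol <- 1e-10 * (max(abs(r)) + 1)
  z <- abs(e) <= tol
  s_fixed <- ifelse(e > 0, tau, tau - 1)
  s_fixed[z] <- 0
  Fs <- sum(s_fixed)
  Fx <- sum(x * s_fixed)
  nz <- sum(z)
  if (nz == 0L) {
    g <- -Fx
    return(c(g, g))
  }
  # choose s_z in [tau-1, tau] with sum s_z = -Fs; write s_z = (tau-1) + u_z
  xz <- x[z]
  U <- -Fs - nz * (tau - 1)
  U <- min(max(U, 0), nz)
  base <- (tau - 1) * sum(xz)
  greedy <- function(ord) {
    u <- numeric(nz)
    left <- U
    for (i in ord) {
      take <- min(1, left)
      u[i] <- take
      left <- left - take
      if (left <= 0) break
    }
    sum(xz * u)
  }
  smax <- base + greedy(order(xz, decreasing = TRUE))
  smin <- base + greedy(order(xz, decreasing = FALSE))
  c(-(Fx + smax), -(Fx + smin))
}

#' Exact quantile regression line
#'
#' Fits `y = a + b x` by minimising the check-function loss
#' `sum rho_tau(y - a - b x)` exactly. The profiled objective in the slope
#' is convex piecewise linear, so the minimiser is located by bisection on
#' its subgradient sign; the returned line attains the global minimum (for
#' tau = 0.5 this is the least-absolute-deviations line, which always
#' passes through two data points).
#'
#' @param x,y Numeric vectors of equal length (n >= 3); `x` must vary.
#' @param tau Quantile level in (0, 1); 0.5 fits the conditional median.
#' @param method `"compiled"` (default; C++ implementation of the same
#'   algorithm, used by the permutation/bootstrap loops) or `"reference"`
#'   (pure-R implementation).
#' @return List with `intercept`, `slope`, `objective`, `tau`, `n`.
#' @export
#' @examples
#' quantile_fit(1:10, 2 * (1:10) + 1)$slope # exactly 2
quantile_fit <- function(x, y, tau = 0.5, method = c("compiled", "reference")) {
  method <- match.arg(method)
  x <- as.numeric(x); y <- as.numeric(y)
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) abort("quantile_fit needs at least 3 complete observations.")
  if (!is.numeric(tau) || length(tau) != 1L || tau <= 0 || tau >= 1) {
    abort("`tau` must be a single value in (0, 1).")
  }
  if (x_is_constant(x)) abort("`x` is constant; the slope is unidentified.")
  if (method == "compiled") return(qfit_cpp(x, y, tau))

  sgn <- function(b) {
    g <- profile_subgradient(x, y, b, tau)
    if (g[2] < 0) -1L else if (g[1] > 0) 1L else 0L
  }

  # bracket the sign change, starting near the least-squares slope
  xc <- x - mean(x)
  b0 <- sum(xc * (y - mean(y))) / sum(xc^2)
  step <- max(1, 4 * (stats::sd(y) + 1e-12) / (stats::sd(x) + 1e-12))
  s0 <- sgn(b0)
  if (s0 == 0L) {
    b_opt <- b0
  } else {
    lo <- b0; hi <- b0
    guard <- 0L
    if (s0 < 0L) {
      hi <- b0 + step
      while (sgn(hi) < 0L) {
        lo <- hi; hi <- hi + step; step <- step * 2
        guard <- guard + 1L
        if (guard > 200L) abort("quantile_fit: slope bracket failed to close (data may be degenerate).")
      }
    } else {
      lo <- b0 - step
      while (sgn(lo) > 0L) {
        hi <- lo; lo <- lo - step; step <- step * 2
        guard <- guard + 1L
        if (guard > 200L) abort("quantile_fit: slope bracket failed to close (data may be degenerate).")
      }
    }
    # invariant: sgn(lo) <= 0 <= sgn(hi) is approached by shrinking [lo, hi]
    b_opt <- NULL
    for (it in seq_len(200L)) {
      mid <- (lo + hi) / 2
      sm <- sgn(mid)
      if (sm == 0L) { b_opt <- mid; break }
      if (sm < 0L) lo <- mid else hi <- mid
      if (hi - lo < 1e-12 * (1 + abs(lo) + abs(hi))) break
    }
    if (is.null(b_opt)) b_opt <- (lo + hi) / 2
  }
  a_opt <- tau_intercept(y - b_opt * x, tau)
  list(
    intercept = a_opt,
    slope = b_opt,
    objective = sum(rho_tau(y - a_opt - b_opt * x, tau)),
    tau = tau,
    n = n
  )
}

# x with a range this small relative to its magnitude carries no slope
# information (e.g. patristic distances that are all one deep-node value up
# to float noise); treated as constant everywhere.
x_is_constant <- function(x) {
  (max(x) - min(x)) <= 1e-10 * max(1, abs(max(x)), abs(min(x)))
}

# ---- species-level randomization over a pair table ----------------------

pair_subset <- function(pairs, subset) {
  if (identical(subset, "all")) return(pairs)
  lv <- c("reseeder_reseeder", "resprouter_resprouter", "mixed")
  if (!subset %in% lv) {
    abort(paste0("`subset` must be 'all' or one of: ", paste(lv, collapse = ", ")))
  }
  pairs[pairs$guild_combo == subset, , drop = FALSE]
}

lookup_matrix <- function(pairs, name) {
  m <- attr(pairs, "responses")[[name]] %||% attr(pairs, "predictors")[[name]]
  if (is.null(m)) {
    abort(paste0(
      "'", name, "' is not a stored response or predictor; available: ",
      paste(c(names(attr(pairs, "responses")), names(attr(pairs, "predictors"))),
            collapse = ", ")
    ))
  }
  m
}

pair_xy <- function(pairs, predictor, response, subset) {
  sub <- pair_subset(pairs, subset)
  if (nrow(sub) == 0L) abort("subset contains no pairs.")
  X <- lookup_matrix(pairs, predictor)
  Y <- lookup_matrix(pairs, response)
  list(
    a = sub$species_a,
    b = sub$species_b,
    x = X[cbind(sub$species_a, sub$species_b)],
    y = Y[cbind(sub$species_a, sub$species_b)],
    X = X, Y = Y,
    species = sort(unique(c(sub$species_a, sub$species_b)))
  )
}

#' Species-permutation p-value for a pairwise quantile slope
#'
#' Pairs sharing a species are not independent, so p-values from a pair-level
#' test are anticonservative. The null here permutes which species carries
#' which species-level attribute (Mantel-style: tip labels for patristic
#' distances, trait values otherwise), rebuilds every pairwise predictor
#' distance under the relabeling, refits the quantile regression, and
#' compares absolute slopes:
#' `p = (1 + #{|b_perm| >= |b_obs|}) / (B_perm + 1)` (two-sided).
#' Permutation is over the species involved in the analysed subset.
#'
#' @param pairs An `fc_pairs` table from [build_pair_table()].
#' @param predictor Name of a stored predictor (e.g. `"phylo"`, `"height"`,
#'   `"d_soil_nitrate"`).
#' @param response Name of a stored response (`"cij_small"`, `"cij_large"`)
#'   or predictor used as response.
#' @param subset `"all"` or a guild combination label.
#' @param tau Quantile level.
#' @param B_perm Number of permutations.
#' @param seed RNG seed (NULL uses the current stream).
#' @return List with `p_perm`, `slope_obs`, `n_pairs`, `B_perm`.
#' @export
species_permutation_pvalue <- function(pairs, predictor, response = "cij_small",
                                       subset = "all", tau = 0.5,
                                       B_perm = 199, seed = NULL) {
  d <- pair_xy(pairs, predictor, response, subset)
  keep <- is.finite(d$x)
  if (sum(keep) < 3L) abort("fewer than 3 pairs with finite predictor values.")
  obs <- quantile_fit(d$x[keep], d$y[keep], tau)$slope
  sp <- d$species
  if (length(unique(round(d$X[sp, sp], 15))) <= 1L) {
    abort("predictor attribute is constant across species; permutation null undefined.")
  }
  hits <- with_seed(seed, {
    vapply(seq_len(B_perm), function(b) {
      map <- setNames(sample(sp), sp)
      xp <- d$X[cbind(map[d$a], map[d$b])]
      ok <- is.finite(xp)
      if (sum(ok) < 3L || x_is_constant(xp[ok])) return(NA)
      bp <- quantile_fit(xp[ok], d$y[ok], tau)$slope
      abs(bp) >= abs(obs) - 1e-12
    }, logical(1))
  })
  hits <- hits[!is.na(hits)]
  list(
    p_perm = (1 + sum(hits)) / (length(hits) + 1),
    slope_obs = obs,
    n_pairs = sum(keep),
    B_perm = length(hits)
  )
}

#' Species-bootstrap confidence interval for a pairwise quantile slope
#'
#' Resamples species (not pairs) with replacement, rebuilds the pair table
#' from the resampled species — dropping self-pairs and pairs not retained
#' by the geographic filter — refits the quantile regression, and returns
#' the percentile interval of the bootstrap slopes. Resampling the species
#' respects the dependence among pairs that share a species.
#'
#' @inheritParams species_permutation_pvalue
#' @param B_boot Number of bootstrap resamples.
#' @param level Interval coverage (default 0.95).
#' @param max_retry Redraws allowed for degenerate resamples.
#' @return List with `ci_low`, `ci_high`, `slopes` (bootstrap draws).
#' @export
species_bootstrap_ci <- function(pairs, predictor, response = "cij_small",
                                 subset = "all", tau = 0.5, B_boot = 199,
                                 level = 0.95, seed = NULL, max_retry = 100) {
  d <- pair_xy(pairs, predictor, response, subset)
  sp <- d$species
  if (length(sp) < 4L) abort("species bootstrap needs at least 4 distinct species.")
  retained_key <- paste(pmin(d$a, d$b), pmax(d$a, d$b), sep = "|")

  slopes <- with_seed(seed, {
    vapply(seq_len(B_boot), function(bb) {
      for (try in seq_len(max_retry)) {
        draw <- sample(sp, length(sp), replace = TRUE)
        idx <- utils::combn(length(draw), 2)
        a <- draw[idx[1, ]]; b <- draw[idx[2, ]]
        ok <- a != b
        key <- paste(pmin(a, b), pmax(a, b), sep = "|")
        ok <- ok & key %in% retained_key
        a <- a[ok]; b <- b[ok]
        if (length(a) < 3L) next
        xb <- d$X[cbind(a, b)]
        yb <- d$Y[cbind(a, b)]
        fin <- is.finite(xb) & is.finite(yb)
        if (sum(fin) < 3L || x_is_constant(xb[fin])) next
        return(quantile_fit(xb[fin], yb[fin], tau)$slope)
      }
      abort("species bootstrap failed to draw a non-degenerate resample.")
    }, numeric(1))
  })
  alpha <- (1 - level) / 2
  ci <- unname(quantile(slopes, c(alpha, 1 - alpha), type = 7))
  list(ci_low = ci[1], ci_high = ci[2], slopes = slopes)
}

#' Quantile regression of co-occurrence on a pairwise distance
#'
#' One cell of the analysis grid: fits the exact tau-quantile line of a
#' response (co-occurrence at one plot scale) on one pairwise predictor
#' distance within one guild subset, and attaches the species-permutation
#' p-value and the species-bootstrap confidence interval. The reported
#' degrees of freedom follow the `n_pairs - 2` convention. A positive
#' slope means greater distance goes with greater co-occurrence —
#' repulsion; a negative slope means attraction/filtering.
#'
#' @inheritParams species_permutation_pvalue
#' @inheritParams species_bootstrap_ci
#' @return An object of class `fc_quantreg` with [generics::tidy()] and
#'   [generics::glance()] methods.
#' @export
quantreg_cell <- function(pairs, predictor, response = "cij_small",
                          subset = "all", tau = 0.5, B_perm = 199,
                          B_boot = 199, level = 0.95, seed = NULL) {
  d <- pair_xy(pairs, predictor, response, subset)
  keep <- is.finite(d$x) & is.finite(d$y)
  n <- sum(keep)
  if (n < 3L) abort("fewer than 3 usable pairs in this cell.")
  fit <- quantile_fit(d$x[keep], d$y[keep], tau)
  perm <- species_permutation_pvalue(
    pairs, predictor, response, subset, tau, B_perm,
    seed = child_seed(seed, paste0("perm-", predictor, response, subset))
  )
  boot <- species_bootstrap_ci(
    pairs, predictor, response, subset, tau, B_boot, level,
    seed = child_seed(seed, paste0("boot-", predictor, response, subset))
  )
  structure(
    list(
      response = response, predictor = predictor, subset = subset,
      tau = tau, slope = fit$slope, intercept = fit$intercept,
      ci_low = boot$ci_low, ci_high = boot$ci_high, level = level,
      p_perm = perm$p_perm, n_pairs = n, df = n - 2L,
      B_perm = perm$B_perm, B_boot = B_boot, seed = seed,
      boot_slopes = boot$slopes
    ),
    class = "fc_quantreg"
  )
}

#' @export
print.fc_quantreg <- function(x, ...) {
  cat(sprintf(
    "Quantile regression (tau = %.2f): %s ~ %s [%s]\n  slope %.4g (%.4g, %.4g)%s  p_perm = %.4g  (n = %d pairs, df = %d)\n",
    x$tau, x$response, x$predictor, x$subset,
    x$slope, x$ci_low, x$ci_high, significance_stars(x$p_perm),
    x$p_perm, x$n_pairs, x$df
  ))
  invisible(x)
}
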