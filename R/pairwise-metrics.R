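#' Schoener's index of co-occurrence
#'
#' For species i and j surveyed over the same plots,
#' `C_ij = 1 - 0.5 * sum_k |p_ik - p_jk|`, where `p_ik` is species i's
#' abundance in plot k divided by i's total abundance over all plots.
#' `C_ij` is 1 for identical proportional site-use profiles and 0 for
#' disjoint ones, and uses both presence and proportional abundance.
#'
#' @param abund Plots-by-species matrix of nonnegative abundances, or a
#'   tibble with a `plot_id`/`large_plot` id column followed by species
#'   columns.
#' @return Symmetric species-by-species matrix in `[0, 1]` with unit
#'   diagonal.
#' @export
#' @examples
#' a <- cbind(sp1 = c(2, 2, 0), sp2 = c(0, 2, 2))
#' schoener_cij(a)["sp1", "sp2"] # 0.5
schoener_cij <- function(abund) {
  m <- abund_matrix(abund)
  tot <- colSums(m)
  zero <- colnames(m)[tot == 0]
  if (length(zero) > 0) {
    abort(paste0(
      "species with zero total abundance have undefined co-occurrence: ",
      paste(zero, collapse = ", ")
    ))
  }
  p <- sweep(m, 2, tot, "/")
  d <- as.matrix(stats::dist(t(p), method = "manhattan"))
  cij <- 1 - d / 2
  diag(cij) <- 1
  cij
}

abund_matrix <- function(abund) {
  if (is.data.frame(abund)) {
    idcol <- intersect(names(abund), c("plot_id", "large_plot"))
    m <- as.matrix(abund[setdiff(names(abund), idcol)])
    rownames(m) <- if (length(idcol)) abund[[idcol[1]]] else NULL
  } else {
    m <- as.matrix(abund)
  }
  storage.mode(m) <- "double"
  if (any(m < 0) || anyNA(m)) abort("abundances must be nonnegative and complete.")
  m
}

#' Flowering-period overlap dissimilarity
#'
#' The number of months in which both species flower, divided by the
#' shorter of the two flowering periods, subtracted from 1 — so larger
#' values mean more dissimilar flowering schedules, consistent with the
#' other pairwise distances. Month sets are sets (wrap-around seasons such
#' as Nov–Feb are just the set {11, 12, 1, 2}).
#'
#' @param months_i,months_j Integer vectors of flowering months (subsets
#'   of 1..12, nonempty).
#' @return Dissimilarity in `[0, 1]`.
#' @export
#' @examples
#' flowering_overlap_dissim(1:3, 2:4) # 1 - 2/3
flowering_overlap_dissim <- function(months_i, months_j) {
  if (length(months_i) == 0L || length(months_j) == 0L) {
    abort("flowering month sets must be nonempty.")
  }
  mi <- unique(as.integer(months_i)); mj <- unique(as.integer(months_j))
  if (!all(c(mi, mj) %in% 1:12)) abort("flowering months must lie in 1..12.")
  1 - length(intersect(mi, mj)) / min(length(mi), length(mj))
}

flowering_dissim_matrix <- function(flowering, species) {
  n <- length(species)
  m <- matrix(0, n, n, dimnames = list(species, species))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      m[i, j] <- m[j, i] <- flowering_overlap_dissim(flowering[[i]], flowering[[j]])
    }
  }
  m
}

#' Edaphic preference slopes
#'
#' A species' preference for a soil variable is summarised as the ordinary
#' least-squares slope of its log-transformed abundance (`log(n + 1)`,
#' zeros included) on that variable across all small plots — whether or
#' not the slope differs significantly from zero. The slope carries the
#' units 1/(unit of the soil variable), so rescaling a variable rescales
#' its slopes (and the derived pair distances) inversely.
#'
#' @param ds A `survey_dataset`, or a plots-by-species abundance
#'   matrix/tibble when `soil` is supplied.
#' @param soil Optional soil tibble/matrix (plots x variables), aligned
#'   with the abundance rows; taken from `ds` when `ds` is a
#'   `survey_dataset`.
#' @return Tibble with `species` plus one slope column per soil variable.
#' @export
edaphic_preference_slopes <- function(ds, soil = NULL) {
  if (inherits(ds, "survey_dataset")) {
    ab <- abund_matrix(ds$small_abund)
    soil <- as.matrix(ds$soil[fc_soil_vars])
  } else {
    ab <- abund_matrix(ds)
    if (is.null(soil)) abort("`soil` is required when `ds` is not a survey_dataset.")
    soil <- as.data.frame(soil)
    soil <- as.matrix(soil[setdiff(names(soil), "plot_id")])
  }
  y <- log(ab + 1)
  out <- matrix(NA_real_, ncol(ab), ncol(soil),
                dimnames = list(colnames(ab), colnames(soil)))
  for (v in seq_len(ncol(soil))) {
    x <- soil[, v]
    xc <- x - mean(x)
    sxx <- sum(xc^2)
    if (sxx == 0) {
      abort(paste0("soil variable '", colnames(soil)[v], "' is constant; slope undefined."))
    }
    out[, v] <- colSums(xc * y) / sxx
  }
  tibble(species = rownames(out)) |>
    dplyr::bind_cols(as_tibble(as.data.frame(out)))
}

#' Build the pairwise analysis table
#'
#' Assembles one row per retained unordered species pair with the
#' co-occurrence responses at both plot scales and every pairwise
#' predictor distance: patristic distance on the dated tree (Myr), absolute
#' differences in maximum height (m), seed length (mm) and flowering-period
#' length (months), flowering-overlap dissimilarity, and absolute
#' differences in the seven edaphic preference slopes. Pairs involving a
#' species absent from the tree keep their trait/soil distances and get
#' `NA` patristic distance (phylogenetic analyses drop them with a logged
#' count); species with zero total abundance are excluded entirely.
#'
#' The returned tibble carries the species-level structure (response and
#' predictor matrices, guild labels) as attributes so that permutation
#' tests and species bootstraps can rebuild pairwise predictors from
#' species-level relabelings.
#'
#' @param ds A validated `survey_dataset`.
#' @param tree Optional `phylo` covering (a subset of) the species.
#' @param retained Optional pair mask as returned by
#'   [overlapping_pairs()]; defaults to all pairs retained. May cover only
#'   a subset of pairs; uncovered pairs default to retained.
#' @param presence_floor Passed to [aggregate_large_plots()].
#' @param log_traits Use absolute differences of log height / log seed
#'   instead of raw differences.
#' @return A `fc_pairs` tibble; see Details for the attribute payload.
#' @export
build_pair_table <- function(ds, tree = NULL, retained = NULL,
                             presence_floor = 0, log_traits = FALSE) {
  stopifnot(inherits(ds, "survey_dataset"))
  ab_small <- abund_matrix(ds$small_abund)
  keep <- colnames(ab_small)[colSums(ab_small) > 0]
  dropped <- setdiff(colnames(ab_small), keep)
  if (length(dropped) > 0) {
    message("excluding ", length(dropped), " zero-abundance species from pair table: ",
            paste(dropped, collapse = ", "))
  }
  sp <- sort(keep)
  ab_small <- ab_small[, sp, drop = FALSE]
  large <- suppressWarnings(aggregate_large_plots(ds, presence_floor = presence_floor))
  ab_large <- abund_matrix(large)[, sp, drop = FALSE]

  cij_small <- schoener_cij(ab_small)
  cij_large <- schoener_cij(ab_large)

  tr <- ds$traits[match(sp, ds$traits$species), ]
  height <- setNames(tr$height_m, sp)
  seed <- setNames(tr$seed_mm, sp)
  if (log_traits) {
    height <- log(height); seed <- log(seed)
  }
  flower_len <- setNames(vapply(tr$flowering, length, integer(1)), sp)
  guild <- setNames(tr$regen_mode, sp)

  abs_dist <- function(v) {
    m <- abs(outer(v, v, "-")); dimnames(m) <- list(sp, sp); m
  }
  predictors <- list(
    height = abs_dist(height),
    seed = abs_dist(seed),
    flower_len = abs_dist(flower_len),
    flower_overlap = flowering_dissim_matrix(tr$flowering, sp)
  )

  if (!is.null(tree)) {
    tree <- validate_phylogeny(tree)
    on_tree <- intersect(sp, tree$tip.label)
    pd <- matrix(NA_real_, length(sp), length(sp), dimnames = list(sp, sp))
    if (length(on_tree) >= 2) {
      full <- patristic_distances(tree)
      pd[on_tree, on_tree] <- full[on_tree, on_tree]
    }
    off <- setdiff(sp, on_tree)
    if (length(off) > 0) {
      message(length(off), " species not on the tree; their pairs get NA patristic distance: ",
              paste(off, collapse = ", "))
    }
    predictors$phylo <- pd
  }

  slopes <- edaphic_preference_slopes(ds)
  slopes <- slopes[match(sp, slopes$species), ]
  for (v in fc_soil_vars) {
    predictors[[paste0("d_soil_", v)]] <- abs_dist(setNames(slopes[[v]], sp))
  }

  idx <- utils::combn(length(sp), 2)
  pairs <- tibble(
    species_a = sp[idx[1, ]],
    species_b = sp[idx[2, ]]
  )

  if (!is.null(retained)) {
    unknown <- setdiff(
      unique(c(retained$species_a, retained$species_b)),
      colnames(abund_matrix(ds$small_abund))
    )
    if (length(unknown) > 0) {
      abort(paste0("pair mask references unknown species: ", paste(unknown, collapse = ", ")))
    }
    key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "|")
    kept <- setNames(retained$retained, key(retained$species_a, retained$species_b))
    flag <- kept[key(pairs$species_a, pairs$species_b)]
    flag[is.na(flag)] <- TRUE
    pairs <- pairs[flag, ]
  }

  at <- function(m) m[cbind(pairs$species_a, pairs$species_b)]
  pairs <- pairs |>
    mutate(
      cij_small = at(cij_small),
      cij_large = at(cij_large),
      phylo_dist = if (!is.null(predictors$phylo)) at(predictors$phylo) else NA_real_,
      d_height = at(predictors$height),
      d_seed = at(predictors$seed),
      d_flower_len = at(predictors$flower_len),
      d_flower_overlap = at(predictors$flower_overlap),
      guild_combo = guild_combo_label(guild[.data$species_a], guild[.data$species_b])
    )
  for (v in fc_soil_vars) {
    pairs[[paste0("d_soil_", v)]] <- at(predictors[[paste0("d_soil_", v)]])
  }

  structure(
    pairs,
    class = c("fc_pairs", class(pairs)),
    species = sp,
    guild = guild,
    responses = list(cij_small = cij_small, cij_large = cij_large),
    predictors = predictors
  )
}

guild_combo_label <- function(ga, gb) {
  dplyr::case_when(
    ga == "reseeder" & gb == "reseeder" ~ "reseeder_reseeder",
    ga == "resprouter" & gb == "resprouter" ~ "resprouter_resprouter",
    TRUE ~ "mixed"
  )
}

#' @export
print.fc_pairs <- function(x, ...) {
  cat("Pairwise community table:", nrow(x), "retained pairs,",
      length(attr(x, "species")), "species\n")
  NextMethod()
}
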