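#' Analysis configuration
#'
#' Tuning knobs for [run_analysis()]. Defaults follow the package's
#' documented conventions: median regression (`tau = 0.5`), 199
#' permutations and 199 bootstrap resamples per cell, 1000 simulations per
#' D-statistic null, cells skipped below 10 pairs (quantile regression
#' degenerates on tiny pair sets), and no multiple-testing correction
#' across the predictor-by-subset grid (each cell is reported as its own
#' test).
#'
#' @param tau Quantile level(s); the first is used for the report grids.
#' @param B_perm,B_boot Permutations / bootstrap resamples per cell.
#' @param level Bootstrap CI coverage.
#' @param n_sims_d Simulations per D-statistic null.
#' @param min_pairs Minimum pairs for a grid cell to be fitted.
#' @param presence_floor Passed to [aggregate_large_plots()].
#' @param log_traits Use log-scale height/seed differences.
#' @param seed Master seed for all randomized inference.
#' @return An `analysis_config` list.
#' @export
analysis_config <- function(tau = 0.5, B_perm = 199, B_boot = 199,
                            level = 0.95, n_sims_d = 1000, min_pairs = 10,
                            presence_floor = 0, log_traits = FALSE,
                            seed = NULL) {
  structure(
    list(
      tau = tau, B_perm = B_perm, B_boot = B_boot, level = level,
      n_sims_d = n_sims_d, min_pairs = min_pairs,
      presence_floor = presence_floor, log_traits = log_traits, seed = seed
    ),
    class = "analysis_config"
  )
}

fc_subsets <- c("all", "reseeder_reseeder", "resprouter_resprouter", "mixed")
fc_eco_predictors <- c("phylo", "height", "seed", "flower_len", "flower_overlap")

#' Run the full pairwise community-phylogenetics analysis
#'
#' End-to-end orchestration: geographic filtering of species pairs, pair
#' table construction, quantile-regression grids of co-occurrence on the
#' phylogenetic/ecological predictors (`table1`) and on the seven
#' edaphic-preference distances (`table2`) for every guild subset and
#' both plot scales, phylogenetic-signal statistics per trait and
#' soil-preference vector (`table3`), and kappa-optimized node-age
#' divergence summaries per trait. Deterministic given `config$seed`.
#'
#' @param ds A validated `survey_dataset`.
#' @param tree A `phylo` (the consensus tree; used for distances, signal
#'   and contrasts).
#' @param trees Optional list of posterior trees; signal statistics are
#'   then summarised as medians and 2.5/97.5 percentiles across them.
#' @param config An [analysis_config()].
#' @return An `fc_results` list: `pairs`, `table1`, `table2`, `table3`,
#'   `contrasts` (named list of `fc_contrasts`), `cells` (the fitted
#'   `fc_quantreg` objects), `log` (stage messages).
#' @export
run_analysis <- function(ds, tree, trees = NULL, config = analysis_config()) {
  stopifnot(inherits(ds, "survey_dataset"), inherits(config, "analysis_config"))
  tree <- validate_phylogeny(tree)
  logm <- character(0)
  note <- function(...) {
    msg <- sprintf(...)
    logm <<- c(logm, msg)
    message(msg)
  }

  retained <- NULL
  if (!is.null(ds$occurrences)) {
    retained <- overlapping_pairs(ds$occurrences,
                                  species = species_of(ds$small_abund))
    note("geographic filter: %d of %d pairs retained",
         sum(retained$retained), nrow(retained))
  }
  pairs <- suppressMessages(build_pair_table(
    ds, tree, retained,
    presence_floor = config$presence_floor, log_traits = config$log_traits
  ))
  note("pair table: %d pairs over %d species (%d species on tree)",
       nrow(pairs), length(attr(pairs, "species")),
       length(intersect(attr(pairs, "species"), tree$tip.label)))

  tau <- config$tau[1]
  soil_predictors <- paste0("d_soil_", fc_soil_vars)
  grid <- function(predictors) {
    rows <- list()
    cells <- list()
    for (subset in fc_subsets) {
      sub <- pair_subset(pairs, subset)
      for (response in c("cij_small", "cij_large")) {
        scale_ha <- if (response == "cij_small") 0.04 else 4
        for (pred in predictors) {
          x <- lookup_matrix(pairs, pred)[cbind(sub$species_a, sub$species_b)]
          n_ok <- sum(is.finite(x))
          if (n_ok < config$min_pairs) {
            rows[[length(rows) + 1]] <- tibble(
              subset = subset, scale_ha = scale_ha, predictor = pred,
              n_pairs = n_ok, df = NA_integer_, slope = NA_real_,
              ci_low = NA_real_, ci_high = NA_real_, p_perm = NA_real_,
              stars = NA_character_,
              skipped = sprintf("skipped: n=%d < minimum %d", n_ok, config$min_pairs)
            )
            next
          }
          cell <- quantreg_cell(
            pairs, pred, response, subset, tau,
            B_perm = config$B_perm, B_boot = config$B_boot,
            level = config$level,
            seed = child_seed(config$seed, paste(pred, response, subset))
          )
          cells[[paste(pred, response, subset, sep = ".")]] <- cell
          rows[[length(rows) + 1]] <- tibble(
            subset = subset, scale_ha = scale_ha, predictor = pred,
            n_pairs = cell$n_pairs, df = cell$df, slope = cell$slope,
            ci_low = cell$ci_low, ci_high = cell$ci_high,
            p_perm = cell$p_perm, stars = significance_stars(cell$p_perm),
            skipped = NA_character_
          )
        }
      }
    }
    list(table = bind_rows(rows), cells = cells)
  }

  g1 <- grid(fc_eco_predictors)
  g2 <- grid(soil_predictors)

  # --- phylogenetic signal summaries ---
  tr_traits <- signal_trait_vectors(ds)
  sp_on_tree <- intersect(names(tr_traits$height_m), tree$tip.label)
  stree <- ape::keep.tip(tree, sp_on_tree)
  strees <- if (is.null(trees)) list(stree) else {
    lapply(trees, function(t) ape::keep.tip(validate_phylogeny(t), sp_on_tree))
  }

  lam_row <- function(name, values) {
    res <- signal_across_trees(strees, function(t) {
      r <- pagel_lambda_ml(t, values[t$tip.label], trait_name = name)
      c(estimate = r$lambda_ml, p_labile = r$p_labile, p_brownian = r$p_brownian)
    })
    s <- res$summary
    tibble(
      trait = name, statistic = "lambda",
      estimate = s$median[s$statistic == "estimate"],
      q025 = s$q025[s$statistic == "estimate"],
      q975 = s$q975[s$statistic == "estimate"],
      p_labile = s$median[s$statistic == "p_labile"],
      p_brownian = s$median[s$statistic == "p_brownian"]
    )
  }

  table3 <- bind_rows(
    lam_row("height", tr_traits$height_m),
    lam_row("seed", tr_traits$seed_mm),
    lam_row("flower_len", tr_traits$flower_len),
    {
      res <- signal_across_trees(strees, function(t) {
        r <- d_statistic(t, tr_traits$regen01[t$tip.label],
                         n_sims = config$n_sims_d,
                         seed = child_seed(config$seed, "dstat"))
        c(estimate = r$D, p_labile = r$p_random, p_brownian = r$p_brownian)
      })
      s <- res$summary
      tibble(
        trait = "regen_mode", statistic = "D",
        estimate = s$median[s$statistic == "estimate"],
        q025 = s$q025[s$statistic == "estimate"],
        q975 = s$q975[s$statistic == "estimate"],
        p_labile = s$median[s$statistic == "p_labile"],
        p_brownian = s$median[s$statistic == "p_brownian"]
      )
    },
    {
      fo <- flowering_overlap_signal(
        pairs, tau = tau, B_perm = config$B_perm, B_boot = config$B_boot,
        seed = child_seed(config$seed, "flower-signal")
      )
      tibble(
        trait = "flower_overlap", statistic = "qreg_slope",
        estimate = fo$slope, q025 = fo$ci_low, q975 = fo$ci_high,
        p_labile = fo$p_perm, p_brownian = NA_real_
      )
    },
    bind_rows(lapply(fc_soil_vars, function(v) {
      lam_row(paste0("pref_", v), tr_traits$soil_slopes[[v]])
    }))
  )

  # --- node-age divergence on the consensus tree ---
  contr <- list()
  for (nm in c("height_m", "seed_mm", "flower_len")) {
    contr[[nm]] <- node_age_divergence(stree, tr_traits[[nm]][stree$tip.label])
  }
  for (v in fc_soil_vars) {
    contr[[paste0("pref_", v)]] <-
      node_age_divergence(stree, tr_traits$soil_slopes[[v]][stree$tip.label])
  }

  structure(
    list(
      pairs = pairs, table1 = g1$table, table2 = g2$table, table3 = table3,
      contrasts = contr, cells = c(g1$cells, g2$cells),
      config = config, log = logm
    ),
    class = "fc_results"
  )
}

signal_trait_vectors <- function(ds) {
  tr <- ds$traits
  slopes <- suppressWarnings(edaphic_preference_slopes(ds))
  list(
    height_m = setNames(tr$height_m, tr$species),
    seed_mm = setNames(tr$seed_mm, tr$species),
    flower_len = setNames(vapply(tr$flowering, length, integer(1)), tr$species),
    regen01 = setNames(as.numeric(tr$regen_mode == "reseeder"), tr$species),
    soil_slopes = lapply(
      setNames(fc_soil_vars, fc_soil_vars),
      function(v) setNames(slopes[[v]], slopes$species)
    )
  )
}

#' @export
print.fc_results <- function(x, ...) {
  cat("Community phylogenetics results\n")
  cat("  pairs:", nrow(x$pairs), "\n")
  cat("  table1 cells:", nrow(x$table1),
      "| table2 cells:", nrow(x$table2),
      "| signal rows:", nrow(x$table3), "\n")
  invisible(x)
}

#' Write report tables mirroring the analysis output structure
#'
#' Writes `pair_table.csv`, `table1_like.csv`, `table2_like.csv`,
#' `table3_like.csv`, one `contrasts_<trait>.csv` per trait, and a
#' `manifest.json` recording the configuration, seed and md5 hashes of
#' every file written. Tables are tidy (one row per cell) with slope,
#' bootstrap interval, permutation p-value, significance stars and
#' degrees of freedom per cell.
#'
#' @param results An `fc_results` object.
#' @param outdir Output directory (created if needed).
#' @param plots Also write PNG node-age divergence plots.
#' @return Invisibly, the manifest list.
#' @export
render_reports <- function(results, outdir, plots = FALSE) {
  stopifnot(inherits(results, "fc_results"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(outdir)) abort(paste0("cannot create output directory: ", outdir))
  files <- character(0)
  wr <- function(df, name) {
    p <- file.path(outdir, name)
    readr::write_csv(df, p)
    files <<- c(files, p)
  }
  wr(as_tibble(results$pairs), "pair_table.csv")
  wr(results$table1, "table1_like.csv")
  wr(results$table2, "table2_like.csv")
  wr(results$table3, "table3_like.csv")
  for (nm in names(results$contrasts)) {
    cs <- results$contrasts[[nm]]
    out <- tibble(
      node = cs$node, age = cs$age,
      abs_std_contrast = cs$abs_std_contrast,
      outlier = cs$outlier, kappa = attr(cs, "kappa")
    )
    wr(out, paste0("contrasts_", nm, ".csv"))
  }
  if (plots) {
    for (nm in names(results$contrasts)) {
      p <- ggplot2::autoplot(results$contrasts[[nm]]) +
        ggplot2::ggtitle(nm)
      ggplot2::ggsave(file.path(outdir, paste0("contrasts_", nm, ".png")),
                      p, width = 5, height = 4, dpi = 120)
    }
  }
  manifest <- list(
    package = "firecomm",
    version = as.character(utils::packageVersion("firecomm")),
    seed = results$config$seed,
    config = results$config[setdiff(names(results$config), "seed")],
    log = results$log,
    files = lapply(
      setNames(basename(files), basename(files)),
      function(f) unname(tools::md5sum(file.path(outdir, f)))
    )
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
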