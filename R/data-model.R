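#' Soil variables measured per small plot
#'
#' Column names used throughout the package for the seven edaphic
#' variables: calcium, potassium, phosphorus, nitrate, pH, organic matter
#' and silicon.
#' @export
fc_soil_vars <- c(
  "calcium", "potassium", "phosphorus", "nitrate",
  "ph", "organic_matter", "silicon"
)

#' Assemble and validate a nested survey dataset
#'
#' Bundles the four tables of a nested vegetation survey: abundance counts
#' in small plots (4 subplots nested in each large plot), soil chemistry
#' per small plot, per-species ecological traits, and georeferenced
#' occurrence records. Small-plot ids carry the nesting as
#' `"L07_S3"` (large plot `L07`, subplot 3). Large-plot presence is derived
#' from the subplot counts when not supplied explicitly (a supplied table
#' may add presences with no subplot individuals, mirroring surveys that
#' record presence at the large scale only).
#'
#' @param small_abund Tibble with a `plot_id` column (`"<large>_S<k>"`) and
#'   one nonnegative integer column per species.
#' @param soil Tibble with `plot_id` plus the seven columns in
#'   [fc_soil_vars], aligned 1:1 with `small_abund`.
#' @param traits Tibble with columns `species`, `height_m` (> 0; the code
#'   `"prostrate"` is accepted by [load_dataset()] and mapped to 0.2 m),
#'   `seed_mm` (> 0), `regen_mode` (`"reseeder"` or `"resprouter"`) and
#'   `flowering` (list-column of integer month vectors, subsets of 1..12,
#'   nonempty).
#' @param occurrences Tibble with columns `species`, `lon`, `lat`
#'   (WGS84 decimal degrees), or `NULL` if no geographic filtering is wanted.
#' @param large_presence Optional tibble with `large_plot` plus one logical
#'   column per species.
#' @return A validated object of class `survey_dataset` (a named list of
#'   tibbles plus the nesting map).
#' @export
survey_dataset <- function(small_abund, soil, traits, occurrences = NULL,
                           large_presence = NULL) {
  small_abund <- as_tibble(small_abund)
  soil <- as_tibble(soil)
  traits <- as_tibble(traits)
  if (!is.null(occurrences)) occurrences <- as_tibble(occurrences)

  nesting <- parse_nesting(small_abund$plot_id)

  if (is.null(large_presence)) {
    sp <- species_of(small_abund)
    pres <- rowsum(as.data.frame(small_abund[sp]), group = nesting$large_plot) > 0
    large_presence <- tibble(large_plot = rownames(pres)) |>
      dplyr::bind_cols(as_tibble(as.data.frame(pres)))
  } else {
    large_presence <- as_tibble(large_presence)
  }

  ds <- structure(
    list(
      small_abund = small_abund,
      large_presence = large_presence,
      nesting = nesting,
      soil = soil,
      traits = traits,
      occurrences = occurrences
    ),
    class = "survey_dataset"
  )
  validate_survey_dataset(ds)
}

species_of <- function(abund) setdiff(names(abund), "plot_id")

parse_nesting <- function(plot_ids) {
  m <- regmatches(plot_ids, regexec("^(.+)_S(\\d+)$", plot_ids))
  bad <- vapply(m, length, integer(1)) != 3L
  if (any(bad)) {
    abort(paste0(
      "small plot ids must look like '<large>_S<k>'; offending ids: ",
      paste(plot_ids[bad], collapse = ", ")
    ))
  }
  tibble(
    plot_id = plot_ids,
    large_plot = vapply(m, `[`, character(1), 2L),
    subplot = as.integer(vapply(m, `[`, character(1), 3L))
  )
}

#' Validate a survey dataset against its invariants
#'
#' Checks: abundance counts are nonnegative integers; every surveyed
#' species has a trait row; heights and seed lengths are positive;
#' regeneration modes are reseeder/resprouter; flowering month sets are
#' nonempty subsets of 1..12; each large plot has exactly 4 subplots; soil
#' rows align 1:1 with small plots with no missing values. Species present
#' in `traits` but absent from every plot are retained with a warning
#' (they are excluded from co-occurrence, which is undefined for an
#' all-zero abundance profile).
#'
#' @param ds A `survey_dataset`.
#' @return `ds`, invisibly validated (errors describe every violation).
#' @export
validate_survey_dataset <- function(ds) {
  stopifnot(inherits(ds, "survey_dataset"))
  ab <- ds$small_abund
  sp <- species_of(ab)
  if (length(sp) == 0L) abort("abundance table has no species columns.")

  av <- as.matrix(ab[sp])
  if (anyNA(av)) abort("abundance table contains missing values.")
  if (any(av < 0)) abort("abundance table contains negative counts.")
  if (any(av != round(av))) abort("abundance counts must be integers.")

  counts <- table(ds$nesting$large_plot)
  if (any(counts != 4L)) {
    abort(paste0(
      "each large plot must contain exactly 4 subplots; offending: ",
      paste(names(counts)[counts != 4L], collapse = ", ")
    ))
  }

  if (!identical(ds$soil$plot_id, ab$plot_id)) {
    abort("soil rows must align 1:1 with small-plot abundance rows (same plot_id order).")
  }
  sv <- as.matrix(ds$soil[fc_soil_vars])
  if (anyNA(sv) || any(!is.finite(sv))) {
    abort("soil table has missing or non-finite values; impute upstream.")
  }

  tr <- ds$traits
  need <- c("species", "height_m", "seed_mm", "regen_mode", "flowering")
  if (!all(need %in% names(tr))) {
    abort(paste0("trait table must have columns: ", paste(need, collapse = ", ")))
  }
  missing_tr <- setdiff(sp, tr$species)
  if (length(missing_tr) > 0) {
    abort(paste0(
      "species in abundance table missing from traits: ",
      paste(missing_tr, collapse = ", ")
    ))
  }
  if (any(!is.finite(tr$height_m)) || any(tr$height_m <= 0)) {
    abort("trait heights must be positive (code 'prostrate' as 0.2 m at load time).")
  }
  if (any(!is.finite(tr$seed_mm)) || any(tr$seed_mm <= 0)) {
    abort("seed lengths must be positive.")
  }
  if (!all(tr$regen_mode %in% c("reseeder", "resprouter"))) {
    abort("regen_mode must be 'reseeder' or 'resprouter'.")
  }
  okfl <- vapply(tr$flowering, function(f) {
    length(f) >= 1L && all(f %in% 1:12) && !anyNA(f)
  }, logical(1))
  if (!all(okfl)) {
    abort(paste0(
      "flowering month sets must be nonempty subsets of 1..12; offending species: ",
      paste(tr$species[!okfl], collapse = ", ")
    ))
  }

  lp <- ds$large_presence
  if (!setequal(setdiff(names(lp), "large_plot"), sp)) {
    abort("large-plot presence table must cover exactly the surveyed species.")
  }
  if (!setequal(lp$large_plot, unique(ds$nesting$large_plot))) {
    abort("large-plot presence rows must match the large plots in the nesting.")
  }

  zero_total <- sp[colSums(av) == 0]
  if (length(zero_total) > 0) {
    warn(paste0(
      "species with zero total abundance retained but excluded from co-occurrence: ",
      paste(zero_total, collapse = ", ")
    ))
  }

  if (!is.null(ds$occurrences)) {
    occ <- ds$occurrences
    if (!all(c("species", "lon", "lat") %in% names(occ))) {
      abort("occurrence table must have columns species, lon, lat.")
    }
    if (anyNA(occ$lon) || anyNA(occ$lat)) abort("occurrence coordinates must be complete.")
  }
  ds
}

#' Load a survey dataset from CSV files
#'
#' Readers for the plain-text bundle this package writes and consumes:
#' a small-plot abundance CSV (plots as rows, species as columns, plot ids
#' `"<large>_S<k>"`), a trait CSV (`species, height_m, seed_mm, regen_mode,
#' flowering_months` with months `;`-separated, height optionally coded
#' `"prostrate"` which becomes 0.2 m), a soil CSV (`plot_id` + the seven
#' [fc_soil_vars]), an occurrence CSV (`species, lon, lat`) and optionally
#' a large-plot presence CSV.
#'
#' @param paths Named list/vector of file paths with elements `abundance`,
#'   `traits`, `soil`, optionally `occurrences` and `presence`.
#' @return A validated `survey_dataset`.
#' @export
load_dataset <- function(paths) {
  paths <- as.list(paths)
  need <- c("abundance", "traits", "soil")
  if (!all(need %in% names(paths))) {
    abort(paste0("`paths` must name files for: ", paste(need, collapse = ", ")))
  }
  rd <- function(p) readr::read_csv(p, show_col_types = FALSE, progress = FALSE)

  ab <- rd(paths$abundance)
  traits_raw <- rd(paths$traits)
  soil <- rd(paths$soil)
  occ <- if (!is.null(paths$occurrences)) rd(paths$occurrences) else NULL

  height <- traits_raw$height_m
  if (is.character(height)) {
    pro <- tolower(trimws(height)) == "prostrate"
    height[pro] <- "0.2"
    height <- suppressWarnings(as.numeric(height))
  }
  flowering <- lapply(strsplit(as.character(traits_raw$flowering_months), "[;, ]+"), function(x) {
    sort(unique(as.integer(x[nzchar(x)])))
  })
  traits <- tibble(
    species = traits_raw$species,
    height_m = height,
    seed_mm = as.numeric(traits_raw$seed_mm),
    regen_mode = as.character(traits_raw$regen_mode),
    flowering = flowering
  )

  pres <- NULL
  if (!is.null(paths$presence)) {
    pres <- rd(paths$presence)
    pres <- dplyr::mutate(pres, dplyr::across(-"large_plot", as.logical))
  }
  survey_dataset(ab, soil, traits, occurrences = occ, large_presence = pres)
}

#' Write a survey dataset to a directory of CSV files
#'
#' Inverse of [load_dataset()]; writes `abundance.csv`, `traits.csv`,
#' `soil.csv`, `presence.csv` and (if present) `occurrences.csv`.
#'
#' @param ds A `survey_dataset`.
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_dataset <- function(ds, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(ds$small_abund, file.path(dir, "abundance.csv"))
  readr::write_csv(ds$soil, file.path(dir, "soil.csv"))
  traits_out <- dplyr::mutate(
    ds$traits,
    flowering_months = vapply(.data$flowering, paste, character(1), collapse = ";")
  ) |> dplyr::select(-"flowering")
  readr::write_csv(traits_out, file.path(dir, "traits.csv"))
  readr::write_csv(ds$large_presence, file.path(dir, "presence.csv"))
  if (!is.null(ds$occurrences)) {
    readr::write_csv(ds$occurrences, file.path(dir, "occurrences.csv"))
  }
  invisible(dir)
}

#' Aggregate subplot abundances to the large-plot scale
#'
#' Large-plot abundance of a species is the arithmetic mean of its counts
#' over the 4 subplots nested in that plot. A species recorded as present
#' at the large-plot scale but with no subplot individuals contributes
#' `presence_floor` (default 0, with a warning), since an abundance for it
#' was never measured.
#'
#' @param ds A `survey_dataset`.
#' @param presence_floor Nominal abundance assigned to presence-only
#'   records at the large-plot scale.
#' @return Tibble with `large_plot` plus one numeric column per species.
#' @export
#' @examples
#' # subplot counts (0, 0, 2, 6) average to 2 at the large-plot scale
aggregate_large_plots <- function(ds, presence_floor = 0) {
  stopifnot(inherits(ds, "survey_dataset"))
  sp <- species_of(ds$small_abund)
  av <- as.matrix(ds$small_abund[sp])
  g <- ds$nesting$large_plot
  means <- rowsum(av, group = g) / 4

  lp <- ds$large_presence
  pres <- as.matrix(lp[sp]) * 1
  rownames(pres) <- lp$large_plot
  pres <- pres[rownames(means), , drop = FALSE]

  floor_cells <- pres > 0 & means == 0
  if (any(floor_cells)) {
    warn(sprintf(
      "%d large-plot presence record(s) had no subplot individuals; assigned abundance %g",
      sum(floor_cells), presence_floor
    ))
    means[floor_cells] <- presence_floor
  }
  tibble(large_plot = rownames(means)) |>
    dplyr::bind_cols(as_tibble(as.data.frame(means)))
}
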