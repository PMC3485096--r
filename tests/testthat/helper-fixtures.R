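# Shared fixtures, all built in code.

# A tiny hand-made survey: 2 large plots x 4 subplots, 3 species.
tiny_dataset <- function() {
  plots <- c(paste0("L01_S", 1:4), paste0("L02_S", 1:4))
  survey_dataset(
    small_abund = tibble::tibble(
      plot_id = plots,
      spA = c(2L, 1L, 0L, 1L, 0L, 0L, 0L, 0L),
      spB = c(0L, 0L, 2L, 6L, 1L, 1L, 1L, 1L),
      spC = c(1L, 1L, 1L, 1L, 2L, 2L, 0L, 0L)
    ),
    soil = tibble::tibble(
      plot_id = plots,
      calcium = c(300, 310, 290, 305, 280, 285, 295, 300),
      potassium = c(40, 42, 38, 41, 39, 40, 43, 37),
      phosphorus = c(5, 5.5, 4.5, 5.2, 4.8, 5.1, 5.3, 4.9),
      nitrate = c(2, 2.2, 1.8, 2.1, 1.9, 2.0, 2.3, 1.7),
      ph = c(5.5, 5.6, 5.4, 5.5, 5.3, 5.6, 5.7, 5.2),
      organic_matter = c(2.5, 2.6, 2.4, 2.5, 2.3, 2.6, 2.7, 2.2),
      silicon = c(20, 21, 19, 20.5, 19.5, 20, 21.5, 18.5)
    ),
    traits = tibble::tibble(
      species = c("spA", "spB", "spC"),
      height_m = c(0.2, 1.5, 4),
      seed_mm = c(3, 5, 12),
      regen_mode = c("reseeder", "reseeder", "resprouter"),
      flowering = list(1:3, 2:4, c(7L, 8L))
    ),
    occurrences = tibble::tibble(
      species = rep(c("spA", "spB", "spC"), each = 4),
      lon = c(116, 117, 116, 117, 116.5, 117.5, 116.5, 117.5, 116, 117.5, 117, 116.2),
      lat = c(-33, -33, -34, -34, -33.5, -33.5, -34.5, -34.5, -33, -34, -33.2, -34.4)
    )
  )
}

# Random ultrametric tree + Brownian trait, for property loops.
random_tree <- function(n, seed) simulate_yule_tree(n, birth_rate = 0.1, seed = seed)

# An artificial pair structure with a known species-level attribute and a
# response matrix, wearing the fc_pairs interface (used to test the
# randomization machinery in isolation from the survey pipeline).
make_pair_fixture <- function(attr_values, y_matrix, retained = NULL) {
  sp <- names(attr_values)
  D <- abs(outer(attr_values, attr_values, "-"))
  dimnames(D) <- list(sp, sp)
  dimnames(y_matrix) <- list(sp, sp)
  idx <- utils::combn(length(sp), 2)
  pairs <- tibble::tibble(
    species_a = sp[idx[1, ]],
    species_b = sp[idx[2, ]],
    guild_combo = "mixed"
  )
  if (!is.null(retained)) pairs <- pairs[retained, ]
  structure(
    pairs,
    class = c("fc_pairs", class(pairs)),
    species = sp,
    responses = list(y = y_matrix),
    predictors = list(attr = D)
  )
}

# points weakly inside a convex polygon (CCW vertices); vectorised
points_in_convex <- function(pts, verts) {
  n <- nrow(verts)
  inside <- rep(TRUE, nrow(pts))
  for (i in seq_len(n)) {
    a <- verts[i, ]; b <- verts[if (i == n) 1 else i + 1, ]
    cr <- (b[1] - a[1]) * (pts[, 2] - a[2]) - (b[2] - a[2]) * (pts[, 1] - a[1])
    inside <- inside & cr >= 0
  }
  inside
}

point_in_convex <- function(p, verts) {
  points_in_convex(matrix(p, ncol = 2), verts)[1]
}
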