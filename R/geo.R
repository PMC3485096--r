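#' Minimum convex polygon around occurrence records
#'
#' Convex hull of a species' occurrence records, used as an
#' extent-of-occurrence proxy. Geometry is planar on raw decimal degrees:
#' the hulls are used only to decide whether two species' ranges overlap,
#' not to report areas, and over a few-hundred-km study region the
#' distortion does not change overlap decisions in practice. Fewer than 3
#' distinct non-collinear points give a degenerate hull, which is buffered
#' by `eps` into a small rectangle and flagged.
#'
#' @param points Two-column matrix or data frame of (lon, lat).
#' @param species Optional species id attached to the polygon.
#' @param eps Buffer (degrees) applied to degenerate hulls.
#' @return A `range_polygon`: list with `species`, `vertices`
#'   (counter-clockwise, one row per vertex), `degenerate` flag.
#' @export
minimum_convex_polygon <- function(points, species = NULL, eps = 0.01) {
  pts <- as.matrix(as.data.frame(points)[, 1:2])
  storage.mode(pts) <- "double"
  if (nrow(pts) == 0L) abort("at least one occurrence point is required.")
  if (anyNA(pts)) abort("occurrence points must not contain NA.")
  pts <- unique(pts)

  degenerate <- FALSE
  if (nrow(pts) < 3L || all_collinear(pts)) {
    verts <- buffer_degenerate(pts, eps)
    degenerate <- TRUE
  } else {
    idx <- grDevices::chull(pts[, 1], pts[, 2])
    verts <- pts[idx, , drop = FALSE]
    verts <- ensure_ccw(verts)
  }
  structure(
    list(species = species, vertices = unname(verts), degenerate = degenerate),
    class = "range_polygon"
  )
}

all_collinear <- function(pts) {
  if (nrow(pts) < 3L) return(TRUE)
  p1 <- pts[1, ]; p2 <- pts[2, ]
  d <- pts[-(1:2), , drop = FALSE]
  cross <- (p2[1] - p1[1]) * (d[, 2] - p1[2]) - (p2[2] - p1[2]) * (d[, 1] - p1[1])
  scale <- max(abs(pts)) + 1
  all(abs(cross) < 1e-12 * scale^2)
}

# Buffer a point or segment into an eps-rectangle (a valid convex polygon).
buffer_degenerate <- function(pts, eps) {
  if (nrow(pts) == 1L) {
    p <- pts[1, ]
    return(rbind(
      p + c(-eps, -eps), p + c(eps, -eps), p + c(eps, eps), p + c(-eps, eps)
    ))
  }
  # extreme points of the collinear set
  i <- which.min(pts[, 1] + 1e-9 * pts[, 2])
  j <- which.max(pts[, 1] + 1e-9 * pts[, 2])
  a <- pts[i, ]; b <- pts[j, ]
  u <- b - a
  len <- sqrt(sum(u^2))
  if (len == 0) return(buffer_degenerate(pts[1, , drop = FALSE], eps))
  u <- u / len
  v <- c(-u[2], u[1])
  rbind(
    a - eps * u - eps * v, b + eps * u - eps * v,
    b + eps * u + eps * v, a - eps * u + eps * v
  )
}

ensure_ccw <- function(verts) {
  if (signed_area(verts) < 0) verts[rev(seq_len(nrow(verts))), , drop = FALSE] else verts
}

signed_area <- function(v) {
  x <- v[, 1]; y <- v[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  sum(x * yn - xn * y) / 2
}

#' Area of a range polygon
#' @param poly A `range_polygon`.
#' @return Planar area in squared degrees.
#' @export
polygon_area <- function(poly) {
  abs(signed_area(poly$vertices))
}

# Sutherland-Hodgman clipping of convex polygon `subj` by convex `clip`
# (both CCW). Returns a vertex matrix, possibly with < 3 rows.
clip_convex <- function(subj, clip) {
  out <- subj
  nc <- nrow(clip)
  for (k in seq_len(nc)) {
    if (nrow(out) == 0L) break
    a <- clip[k, ]
    b <- clip[if (k == nc) 1L else k + 1L, ]
    inp <- out
    out <- matrix(numeric(0), ncol = 2)
    n <- nrow(inp)
    side <- (b[1] - a[1]) * (inp[, 2] - a[2]) - (b[2] - a[2]) * (inp[, 1] - a[1])
    for (i in seq_len(n)) {
      j <- if (i == 1L) n else i - 1L
      cur_in <- side[i] >= 0
      prev_in <- side[j] >= 0
      if (cur_in != prev_in) {
        t <- side[j] / (side[j] - side[i])
        out <- rbind(out, inp[j, ] + t * (inp[i, ] - inp[j, ]))
      }
      if (cur_in) out <- rbind(out, inp[i, ])
    }
  }
  out
}

#' Do two species ranges overlap?
#'
#' True iff the intersection of the two convex range polygons has positive
#' area; polygons that merely touch along a boundary or at a point do not
#' count as overlapping.
#'
#' @param a,b `range_polygon` objects.
#' @return Logical scalar.
#' @export
ranges_overlap <- function(a, b) {
  stopifnot(inherits(a, "range_polygon"), inherits(b, "range_polygon"))
  va <- a$vertices; vb <- b$vertices
  # bounding-box reject
  if (max(va[, 1]) < min(vb[, 1]) || max(vb[, 1]) < min(va[, 1]) ||
      max(va[, 2]) < min(vb[, 2]) || max(vb[, 2]) < min(va[, 2])) {
    return(FALSE)
  }
  inter <- clip_convex(va, vb)
  if (nrow(inter) < 3L) return(FALSE)
  scale <- max(1, polygon_area(a), polygon_area(b))
  abs(signed_area(inter)) > 1e-12 * scale
}

#' Geographically overlapping species pairs
#'
#' Builds a minimum convex polygon per species from its occurrence records
#' and flags, for every unordered species pair, whether the two ranges
#' overlap. Pairs with no overlap are dropped from all downstream distance
#' analyses, so that allopatric speciation history is not mistaken for
#' co-occurrence structure.
#'
#' @param occurrences Tibble with columns `species`, `lon`, `lat`.
#' @param species Optional character vector of species that must be
#'   covered; an error lists any without records.
#' @param eps Degenerate-hull buffer passed to [minimum_convex_polygon()].
#' @return Tibble with columns `species_a`, `species_b`, `retained`
#'   (one row per unordered pair, a < b in the species ordering used).
#' @export
overlapping_pairs <- function(occurrences, species = NULL, eps = 0.01) {
  occ <- as_tibble(occurrences)
  if (!all(c("species", "lon", "lat") %in% names(occ))) {
    abort("`occurrences` must have columns species, lon, lat.")
  }
  sp <- species %||% sort(unique(occ$species))
  missing_sp <- setdiff(sp, unique(occ$species))
  if (length(missing_sp) > 0) {
    abort(paste0(
      "species without occurrence records: ",
      paste(missing_sp, collapse = ", ")
    ))
  }
  polys <- lapply(sp, function(s) {
    minimum_convex_polygon(occ[occ$species == s, c("lon", "lat")], species = s, eps = eps)
  })
  names(polys) <- sp

  n <- length(sp)
  if (n < 2L) abort("need at least two species to form pairs.")
  idx <- utils::combn(n, 2)
  retained <- vapply(seq_len(ncol(idx)), function(k) {
    ranges_overlap(polys[[idx[1, k]]], polys[[idx[2, k]]])
  }, logical(1))
  tibble(
    species_a = sp[idx[1, ]],
    species_b = sp[idx[2, ]],
    retained = retained
  )
}
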