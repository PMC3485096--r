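test_that("hull of unit-square corners plus centre is the square", {
  pts <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1), c(0.5, 0.5))
  poly <- minimum_convex_polygon(pts)
  expect_false(poly$degenerate)
  expect_equal(nrow(poly$vertices), 4)
  expect_equal(polygon_area(poly), 1)
})

test_that("hull matches a brute-force vertex oracle on random point sets", {
  # p is a hull vertex iff some line through p and another point has all
  # remaining points (weakly) on one side, and p is extreme on that line.
  oracle_vertices <- function(pts) {
    n <- nrow(pts)
    on_hull <- logical(n)
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (i == j) next
        d <- pts[j, ] - pts[i, ]
        cr <- (d[1] * (pts[, 2] - pts[i, 2]) - d[2] * (pts[, 1] - pts[i, 1]))
        if (all(cr >= -1e-12) || all(cr <= 1e-12)) {
          on_hull[i] <- TRUE
          break
        }
      }
    }
    on_hull
  }
  set.seed(11)
  for (rep in 1:50) {
    pts <- matrix(runif(2 * sample(5:20, 1)), ncol = 2)
    poly <- minimum_convex_polygon(pts)
    truth <- pts[oracle_vertices(pts), , drop = FALSE]
    got <- poly$vertices
    expect_equal(nrow(got), nrow(truth))
    # same vertex set up to ordering
    key <- function(m) sort(paste(round(m[, 1], 12), round(m[, 2], 12)))
    expect_identical(key(got), key(truth))
  }
})

test_that("degenerate inputs are buffered and flagged", {
  seg <- minimum_convex_polygon(rbind(c(0, 0), c(1, 0)), eps = 0.01)
  expect_true(seg$degenerate)
  expect_equal(nrow(seg$vertices), 4)
  expect_gt(polygon_area(seg), 0)
  pt <- minimum_convex_polygon(rbind(c(3, 3)), eps = 0.01)
  expect_true(pt$degenerate)
  expect_equal(polygon_area(pt), (2 * 0.01)^2)
  col <- minimum_convex_polygon(rbind(c(0, 0), c(1, 1), c(2, 2)))
  expect_true(col$degenerate)
  expect_error(minimum_convex_polygon(matrix(numeric(0), ncol = 2)), "at least one")
})

test_that("overlap decisions are exact on simple cases", {
  sq <- function(x0, y0, s = 1) {
    minimum_convex_polygon(rbind(c(x0, y0), c(x0 + s, y0), c(x0 + s, y0 + s), c(x0, y0 + s)))
  }
  expect_true(ranges_overlap(sq(0, 0), sq(0, 0)))
  expect_false(ranges_overlap(sq(0, 0), sq(5, 5)))
  expect_true(ranges_overlap(sq(0, 0), sq(0.5, 0.5)))
  # boundary touching has zero-area intersection
  expect_false(ranges_overlap(sq(0, 0), sq(1, 0)))
  expect_false(ranges_overlap(sq(0, 0), sq(1, 1)))
})

test_that("overlap agrees with a Monte-Carlo rasterization oracle", {
  set.seed(21)
  rand_poly <- function() {
    c0 <- runif(2, 0, 4)
    minimum_convex_polygon(sweep(matrix(rnorm(2 * 12, sd = 0.8), ncol = 2), 2, c0, "+"))
  }
  for (rep in 1:50) {
    a <- rand_poly(); b <- rand_poly()
    got <- ranges_overlap(a, b)
    # sample over the bounding box of both polygons
    allv <- rbind(a$vertices, b$vertices)
    lo <- apply(allv, 2, min); hi <- apply(allv, 2, max)
    m <- 1e5
    pts <- cbind(runif(m, lo[1], hi[1]), runif(m, lo[2], hi[2]))
    inside <- points_in_convex(pts, a$vertices) & points_in_convex(pts, b$vertices)
    frac <- mean(inside)
    # disagreement is only tolerated for slivers below 1e-3 overlap fraction
    if (frac >= 1e-3) expect_true(got)
    if (!got) expect_lt(frac, 1e-3)
  }
})

test_that("pair retention matches the closed-form disc-overlap truth", {
  set.seed(31)
  n <- 8
  centers <- cbind(runif(n, 0, 6), runif(n, 0, 6))
  radius <- runif(n, 0.5, 1.5)
  # dense boundary sampling: hull converges to the disc
  th <- seq(0, 2 * pi, length.out = 180)[-1]
  occ <- dplyr::bind_rows(lapply(seq_len(n), function(i) {
    tibble::tibble(
      species = sprintf("d%02d", i),
      lon = centers[i, 1] + radius[i] * cos(th),
      lat = centers[i, 2] + radius[i] * sin(th)
    )
  }))
  got <- overlapping_pairs(occ)
  cdist <- as.matrix(dist(centers))
  for (k in seq_len(nrow(got))) {
    i <- as.integer(substr(got$species_a[k], 2, 3))
    j <- as.integer(substr(got$species_b[k], 2, 3))
    margin <- abs(cdist[i, j] - (radius[i] + radius[j]))
    if (margin > 0.05 * (radius[i] + radius[j])) {
      expect_equal(got$retained[k], cdist[i, j] < radius[i] + radius[j],
                   info = paste(i, j))
    }
  }
})

test_that("hull and overlap invariances hold", {
  set.seed(41)
  pts <- matrix(runif(30), ncol = 2)
  p1 <- minimum_convex_polygon(pts)
  # idempotence and order/duplicate invariance
  p2 <- minimum_convex_polygon(p1$vertices)
  expect_equal(polygon_area(p1), polygon_area(p2))
  p3 <- minimum_convex_polygon(rbind(pts[sample(nrow(pts)), ], pts))
  expect_equal(polygon_area(p1), polygon_area(p3))
  # adding an interior point changes nothing
  interior <- colMeans(p1$vertices)
  p4 <- minimum_convex_polygon(rbind(pts, interior))
  expect_equal(polygon_area(p1), polygon_area(p4))
  # symmetry and self-overlap
  q <- minimum_convex_polygon(matrix(runif(20, 0.2, 0.8), ncol = 2))
  expect_identical(ranges_overlap(p1, q), ranges_overlap(q, p1))
  expect_true(ranges_overlap(p1, p1))
})

test_that("species without records are reported", {
  occ <- tibble::tibble(species = "a", lon = c(1, 2, 1), lat = c(1, 1, 2))
  expect_error(overlapping_pairs(occ, species = c("a", "b")), "b")
})
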