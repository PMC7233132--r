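# point-segment distance, written independently for the convex-hull oracle
seg_dist <- function(p, a, b) {
  v <- b - a
  t <- max(0, min(1, sum((p - a) * v) / sum(v * v)))
  sqrt(sum((p - (a + t * v))^2))
}

test_that("the large-alpha limit of a square is the square itself", {
  sq <- cbind(c(0, 1, 1, 0), c(0, 0, 1, 1))
  s <- make_surface(sq, alpha = 100)
  expect_equal(nrow(s$edges), 4L)
  expect_equal(surface_area(s), 1)
  expect_true(surface_contains(s, cbind(0.5, 0.5)))
  expect_false(surface_contains(s, cbind(2, 2)))
})

test_that("an annulus at small alpha has a hole: the center is outside", {
  pts <- rbind(ring_points(90, 1), ring_points(120, 1.5),
               ring_points(100, 1.25))
  s <- make_surface(pts, alpha = 0.2)
  expect_false(surface_contains(s, cbind(0, 0)))
  expect_true(surface_contains(s, cbind(1.25, 0)))
  expect_true(surface_contains(s, cbind(0, -1.3)))
  expect_false(surface_contains(s, cbind(0, 1.8)))
  expect_equal(surface_area(s), pi * (1.5^2 - 1^2), tolerance = 0.02)
})

test_that("generating points are contained in their own alpha shape", {
  pts <- withr::with_seed(51, cbind(runif(150, 0, 10), runif(150, 0, 10)))
  s <- make_surface(pts, alpha = 4)
  interior <- abs(signed_distance(pts, s)$signed_dist_um) > 1e-6
  expect_true(all(surface_contains(s, pts[interior, , drop = FALSE])))
})

test_that("signed distances recover the analytic disk", {
  s <- make_surface(ring_points(256, 1), alpha = 0.2)
  expect_equal(signed_distance(cbind(0, 0), s)$signed_dist_um, -1,
               tolerance = 0.02)
  expect_equal(signed_distance(cbind(2, 0), s)$signed_dist_um, 1,
               tolerance = 0.02)
  v <- ring_points(256, 1)[1, , drop = FALSE]
  expect_equal(signed_distance(v, s)$signed_dist_um, 0)
})

test_that("signed distances recover the analytic sphere in 3D", {
  s <- make_surface(fib_sphere(250, 1), alpha = 0.5)
  expect_equal(s$dim, 3L)
  expect_equal(signed_distance(cbind(0, 0, 0), s)$signed_dist_um, -1,
               tolerance = 0.02)
  expect_equal(signed_distance(cbind(0, 0, 2), s)$signed_dist_um, 1,
               tolerance = 0.02)
  expect_true(surface_contains(s, cbind(0.3, -0.2, 0.4)))
  expect_false(surface_contains(s, cbind(0.9, 0.9, 0.9)))
})

test_that("for convex surfaces exterior distances match an independent hull computation", {
  pts <- withr::with_seed(53, cbind(runif(60, 0, 10), runif(60, 0, 10)))
  s <- make_surface(pts, alpha = 1e6)
  hull <- grDevices::chull(pts)
  qs <- withr::with_seed(54, cbind(runif(40, -10, 20), runif(40, -10, 20)))
  got <- signed_distance(qs, s)$signed_dist_um
  for (i in seq_len(nrow(qs))) {
    if (got[i] <= 0) next
    hd <- min(vapply(seq_along(hull), function(j) {
      a <- pts[hull[j], ]
      b <- pts[hull[if (j == length(hull)) 1 else j + 1], ]
      seg_dist(qs[i, ], a, b)
    }, numeric(1)))
    expect_equal(got[i], hd, tolerance = 1e-9)
  }
})

test_that("degenerate point sets are rejected with a named degeneracy", {
  line <- cbind(1:10, 2 * (1:10))
  expect_error(make_surface(line, alpha = 100), regexp = "collinear",
               class = "tissuemap_geometry_error")
  plane <- cbind(runif(10), runif(10), 0)
  plane[, 3] <- 1  # constant z but nonzero: force 3D
  expect_error(make_surface(plane, alpha = 100, dim = 3),
               regexp = "coplanar", class = "tissuemap_geometry_error")
})

test_that("nearest-object distances are exact", {
  cells <- tibble::tibble(sample_id = "S", phenotype = "A",
                          x_um = 3, y_um = 4, z_um = 0)
  target <- tibble::tibble(sample_id = "S", phenotype = "V",
                           x_um = 0, y_um = 0, z_um = 0)
  expect_equal(nearest_object_distance(cells, target)$nearest_dist_um, 5)
  # cells identical to targets: all zero
  cl <- random_cell_table(50, seed = 55)
  expect_true(all(nearest_object_distance(cl, cl)$nearest_dist_um == 0))
  # brute-force oracle on a random instance
  cl <- random_cell_table(300, seed = 56)
  tg <- random_cell_table(50, seed = 57)
  got <- nearest_object_distance(cl, tg)$nearest_dist_um
  brute <- vapply(seq_len(nrow(cl)), function(i) {
    sqrt(min((tg$x_um - cl$x_um[i])^2 + (tg$y_um - cl$y_um[i])^2 +
               (tg$z_um - cl$z_um[i])^2))
  }, numeric(1))
  expect_equal(got, brute, tolerance = 1e-12)
  expect_error(nearest_object_distance(cl, tg[0, ]),
               class = "tissuemap_empty_error")
})

test_that("the proximal fraction counts cells below the cutoff", {
  d <- c(5, 10, 19.9, 20, 35)
  expect_equal(proximal_fraction(d, 20), 3 / 5)
})

test_that("random control points respect the reference bounds and the seed", {
  ref <- random_cell_table(100, seed = 58, box = c(0, 10), zbox = c(0, 0))
  rdp <- generate_random_points(ref, 500, seed = 9)
  expect_true(all(rdp$x_um >= min(ref$x_um) & rdp$x_um <= max(ref$x_um)))
  expect_true(all(rdp$y_um >= min(ref$y_um) & rdp$y_um <= max(ref$y_um)))
  expect_equal(unique(rdp$phenotype), "RDP")
  expect_true(all(as.matrix(rdp[, channel_names(ref)]) == 0))
  # 2D reference: z copied as a constant
  expect_equal(length(unique(rdp$z_um)), 1L)
  rdp2 <- generate_random_points(ref, 500, seed = 9)
  expect_identical(rdp, rdp2)
  expect_error(generate_random_points(ref, 0),
               class = "tissuemap_parameter_error")
})

test_that("gating retains interior points and drops exterior ones", {
  sq <- make_surface(cbind(c(0, 1, 1, 0), c(0, 0, 1, 1)), alpha = 100)
  pts <- tibble::tibble(sample_id = "S", phenotype = "RDP",
                        x_um = c(0.5, 2, 0.2, 1.0), y_um = c(0.5, 2, 0.9, 1.0),
                        z_um = 0)
  kept <- gate_points(pts, sq)
  expect_equal(nrow(kept), 3L)  # boundary point (1,1) counts as inside
  expect_false(any(kept$x_um == 2))
})

test_that("signed-distance sign always agrees with containment", {
  pts <- withr::with_seed(59, cbind(runif(200, 0, 10), runif(200, 0, 10)))
  s <- make_surface(pts, alpha = 3)
  qs <- withr::with_seed(60, cbind(runif(1000, -2, 12), runif(1000, -2, 12)))
  sd <- signed_distance(qs, s)$signed_dist_um
  inside <- surface_contains(s, qs)
  expect_true(all((sd < 0) == inside | sd == 0))
})
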