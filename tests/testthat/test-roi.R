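test_that("chord closure closes open traces and rejects closed ones", {
  open_l <- polygon_roi(rbind(c(0, 0), c(10, 0), c(10, 10)))
  closed <- close_with_chord(open_l)
  expect_true(closed$closed)
  expect_equal(nrow(closed$vertices), 3L)
  expect_error(close_with_chord(closed), "already closed")
  expect_error(close_with_chord(polygon_roi(rbind(c(0, 0), c(1, 1)))),
               "fewer than 3")
})

test_that("phantom teat trace closes to within 2% of the analytic area", {
  ph <- generate_phantom(phantom_spec(width = 320, height = 240), seed = 2,
                         render = FALSE)
  poly <- close_with_chord(ph$polygons[[1]])
  mask_area <- sum(ph$masks[[1]])
  expect_lt(abs(polygon_area(poly) - mask_area) / mask_area, 0.02)
})

test_that("rasterization counts pixel centers, boundary inclusive", {
  rect <- polygon_roi(rbind(c(0, 0), c(0, 9), c(9, 9), c(9, 0)),
                      closed = TRUE)
  m <- rasterize(rect, c(12, 12))
  expect_equal(sum(m), 100L)
  expect_error(rasterize(polygon_roi(rbind(c(50, 50), c(50, 60), c(60, 55)),
                                     closed = TRUE), c(10, 10)),
               "empty mask")
})

test_that("rasterized triangles match the per-pixel point-in-polygon oracle", {
  for (seed in 1:5) {
    set.seed(seed)
    verts <- matrix(stats::runif(6, 0, 15), 3, 2)
    # keep non-degenerate
    if (abs((verts[2, 1] - verts[1, 1]) * (verts[3, 2] - verts[1, 2]) -
            (verts[3, 1] - verts[1, 1]) * (verts[2, 2] - verts[1, 2])) < 2)
      next
    tri <- polygon_roi(verts, closed = TRUE)
    m <- rasterize(tri, c(16, 16))
    for (r in 0:15) for (c in 0:15)
      expect_identical(m[r + 1, c + 1],
                       oracle_point_in_polygon(r, c, verts),
                       label = sprintf("seed %d pixel (%d,%d)", seed, r, c))
  }
})

test_that("rasterized area converges to the analytic polygon area", {
  # scaled pentagon, >= 1e4 pixels
  ang <- seq(0, 2 * pi, length.out = 6)[-6]
  verts <- cbind(75 + 70 * sin(ang), 75 + 70 * cos(ang))
  poly <- polygon_roi(verts, closed = TRUE)
  m <- rasterize(poly, c(150, 150))
  expect_gt(sum(m), 1e4)
  expect_lt(abs(sum(m) - polygon_area(poly)) / polygon_area(poly), 0.01)
})

test_that("dice matches its defining anchors", {
  a <- matrix(FALSE, 10, 10); a[2:7, 2:7] <- TRUE
  expect_equal(dice(a, a), 1.00)
  # equal-area masks, intersection half of each
  b2 <- matrix(FALSE, 10, 10); b2[1:4, 1:10] <- TRUE  # rows 1-4
  c3 <- matrix(FALSE, 10, 10); c3[3:6, 1:10] <- TRUE  # rows 3-6, overlap 2 rows
  expect_equal(dice(b2, c3), 0.50)
  disj <- matrix(FALSE, 10, 10); disj[9:10, 9:10] <- TRUE
  expect_equal(dice(a, disj), 0)
  expect_error(dice(a, matrix(FALSE, 5, 5)), "shapes")
  expect_error(dice(matrix(FALSE, 2, 2), matrix(FALSE, 2, 2)), "empty")
})

test_that("dice is symmetric and monotone in lost intersection", {
  set.seed(7)
  for (i in 1:20) {
    a <- matrix(stats::runif(64) < 0.5, 8, 8)
    b <- matrix(stats::runif(64) < 0.5, 8, 8)
    if (sum(a) + sum(b) == 0) next
    expect_equal(dice(a, b), dice(b, a))
  }
  a <- matrix(FALSE, 8, 8); a[2:6, 2:6] <- TRUE
  b <- a
  prev <- dice(a, b)
  for (px in which(a & b)[1:5]) {
    # remove an intersection pixel from b, add a disjoint one to keep |b|
    b[px] <- FALSE
    free <- which(!a & !b)[1]
    b[free] <- TRUE
    cur <- dice(a, b)
    expect_lte(cur, prev)
    prev <- cur
  }
})

test_that("dice_summary: zero-variance, determinism, bootstrap convergence", {
  expect_equal(unname(dice_summary(rep(0.9, 10), n_boot = 1000)),
               c(0.9, 0.9, 0.9))
  set.seed(11)
  scores <- pmin(stats::rbeta(25, 20, 1.5), 1)
  s1 <- dice_summary(scores, n_boot = 1000, seed = 5)
  s2 <- dice_summary(scores, n_boot = 1000, seed = 5)
  expect_identical(s1, s2)
  s10 <- dice_summary(scores, n_boot = 10000, seed = 6)
  expect_lt(max(abs(s1[c("lower", "upper")] - s10[c("lower", "upper")])),
            0.01)
  expect_error(dice_summary(numeric(0)), "at least 2")
  expect_error(dice_summary(c(.9, .8), n_boot = 10), "1000")
})

test_that("masks and polygons survive PNG/JSON round trips", {
  m <- matrix(FALSE, 20, 30); m[4:16, 10:25] <- TRUE
  p1 <- withr::local_tempfile(fileext = ".png")
  write_mask_png(m, p1)
  expect_identical(read_mask_png(p1), m)
  poly <- polygon_roi(rbind(c(0.5, 1), c(8, 2.25), c(6, 9)), closed = TRUE,
                      label = "left hind teat")
  p2 <- withr::local_tempfile(fileext = ".json")
  write_polygon_json(poly, p2)
  back <- read_polygon_json(p2)
  expect_equal(unname(back$vertices), unname(poly$vertices))
  expect_identical(back$label, "left hind teat")
  expect_true(back$closed)
})
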