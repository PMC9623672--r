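make_droi <- function(vals, mask = NULL) {
  vals <- as.matrix(vals)
  if (is.null(mask)) mask <- matrix(TRUE, nrow(vals), ncol(vals))
  discretize(vals * 0.1, mask, bin_width = 0.1)
}

test_that("GLCM: constant-ROI anchors forced by the formulas", {
  f <- glcm_features(make_droi(matrix(5, 4, 4)))
  expect_equal(unname(f["Autocorrelation"]), 1)
  expect_equal(unname(f["ClusterShade"]), 0)
  expect_equal(unname(f["SumAverage"]), 2)
  expect_equal(unname(f["Idm"]), 1)
  expect_equal(length(f), 24L)
})

test_that("GLCM of a 2x2 image equals exhaustive symmetric pair counts", {
  d <- make_droi(matrix(c(1, 1, 1, 2), 2, 2))
  mats <- glcm_matrix(d, symmetric = TRUE)
  dirs <- list(c(0L, 1L), c(1L, 0L), c(1L, 1L), c(1L, -1L))
  for (k in seq_along(dirs))
    expect_equal(mats[[k]],
                 oracle_glcm(d$bins, dirs[[k]][1], dirs[[k]][2], d$ng))
})

test_that("cluster shade flips sign under gray-level reflection", {
  set.seed(3)
  for (i in 1:5) {
    vals <- matrix(sample(1:4, 36, replace = TRUE), 6, 6)
    d <- make_droi(vals)
    dr <- make_droi(max(vals) + 1 - vals)
    f <- glcm_features(d); fr <- glcm_features(dr)
    expect_equal(unname(f["ClusterShade"]), -unname(fr["ClusterShade"]),
                 tolerance = 1e-12)
  }
})

test_that("GLRLM: runs on constant lines and checkerboards", {
  # constant 1xN ROI: one horizontal run of length N
  d <- make_droi(matrix(2, 1, 7))
  mats <- glrlm_matrix(d)
  expect_equal(mats[[1]][1, 7], 1)   # horizontal direction, length 7
  expect_equal(sum(mats[[1]]), 1)
  # checkerboard: all horizontal/vertical runs have length 1
  cb <- outer(1:4, 1:4, function(r, c) (r + c) %% 2 + 1)
  dcb <- make_droi(cb)
  mcb <- glrlm_matrix(dcb)
  for (k in 1:2) {
    expect_equal(sum(mcb[[k]][, 1]), 16)
    expect_equal(sum(mcb[[k]]), 16)
  }
})

test_that("GLSZM zones equal a flood-fill oracle on two-level images", {
  set.seed(12)
  for (i in 1:10) {
    vals <- matrix(sample(1:2, 64, replace = TRUE), 8, 8)
    d <- make_droi(vals)
    m <- glszm_matrix(d)
    o <- oracle_glszm(d$bins, d$ng)
    expect_equal(m, o, label = sprintf("case %d", i))
  }
})

test_that("GLDM: constant ROI and the large-alpha limit", {
  d <- make_droi(matrix(4, 3, 3))
  m <- gldm_matrix(d, alpha = 0)
  expect_equal(m[1, 9], 1)   # center pixel: 8 dependent neighbours -> j = 9
  f <- gldm_features(d)
  expect_equal(unname(f["HighGrayLevelEmphasis"]), 1)
  expect_equal(length(f), 14L)
  # alpha -> infinity: dependence = in-mask neighbour count
  set.seed(5)
  vals <- matrix(sample(1:5, 49, replace = TRUE), 7, 7)
  d2 <- make_droi(vals)
  m2 <- gldm_matrix(d2, alpha = 1000L)
  counts <- colSums(m2)
  corner <- 4; edge <- (7 - 2) * 4; inner <- (7 - 2)^2
  expect_equal(unname(counts[4]), corner)   # 3 neighbours -> j = 4
  expect_equal(unname(counts[6]), edge)     # 5 neighbours -> j = 6
  expect_equal(unname(counts[9]), inner)    # 8 neighbours -> j = 9
})

test_that("NGTDM: constant ROI, hand-enumerated deviant center, Strength >= 0", {
  d <- make_droi(matrix(3, 4, 4))
  tb <- ngtdm_table(d)
  expect_equal(tb$s, 0)
  f <- ngtdm_features(d)
  expect_equal(unname(f["Contrast"]), 0)
  expect_equal(unname(f["Strength"]), 0)

  # 3x3 with a deviant center: s from hand-worked neighbour means
  vals <- matrix(1, 3, 3); vals[2, 2] <- 3
  d2 <- make_droi(vals)
  tb2 <- ngtdm_table(d2)
  o <- oracle_ngtdm(d2$bins, d2$ng)
  expect_equal(tb2$s, o$s[o$n > 0])
  expect_equal(tb2$n, o$n[o$n > 0])
  # level 3 (center): |3 - mean(rep(1,8))| = 2; corners see mean (2*1+3)/3
  expect_equal(tb2$s[tb2$level == 3], 2)

  set.seed(9)
  for (i in 1:10) {
    r <- random_droi(i)
    expect_gte(unname(ngtdm_features(r$droi)["Strength"]), 0)
  }
})

test_that("all texture matrices equal brute-force enumeration on random images", {
  dirs <- list(c(0L, 1L), c(1L, 0L), c(1L, 1L), c(1L, -1L))
  for (seed in 1:100) {
    r <- random_droi(seed)
    d <- r$droi
    glcms <- glcm_matrix(d)
    glrlms <- glrlm_matrix(d)
    for (k in seq_along(dirs)) {
      expect_equal(glcms[[k]],
                   oracle_glcm(d$bins, dirs[[k]][1], dirs[[k]][2], d$ng),
                   label = sprintf("glcm seed %d dir %d", seed, k))
      o <- oracle_glrlm(d$bins, dirs[[k]][1], dirs[[k]][2], d$ng,
                        ncol(glrlms[[k]]))
      expect_equal(glrlms[[k]], o,
                   label = sprintf("glrlm seed %d dir %d", seed, k))
    }
    expect_equal(glszm_matrix(d), oracle_glszm(d$bins, d$ng),
                 label = sprintf("glszm seed %d", seed))
    expect_equal(gldm_matrix(d), oracle_gldm(d$bins, d$ng),
                 label = sprintf("gldm seed %d", seed))
    tb <- ngtdm_table(d)
    o <- oracle_ngtdm(d$bins, d$ng)
    expect_equal(tb$n, o$n[o$n > 0], label = sprintf("ngtdm n seed %d", seed))
    expect_equal(tb$s, o$s[o$n > 0], tolerance = 1e-12,
                 label = sprintf("ngtdm s seed %d", seed))
  }
})
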