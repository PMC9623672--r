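# Gray-level texture matrices and their standardized features, computed
# from a discretized ROI (see discretize()). All matrices work on the
# 2D 8-neighbourhood / 4 in-plane directions at distance 1.

glcm_directions <- list(c(0L, 1L), c(1L, 0L), c(1L, 1L), c(1L, -1L))

# shift a matrix by (dr, dc), NA-padded
shift_mat <- function(m, dr, dc) {
  h <- nrow(m); w <- ncol(m)
  out <- matrix(NA, h, w)
  rs <- seq_len(h) + dr; cs <- seq_len(w) + dc
  ok_r <- rs >= 1L & rs <= h; ok_c <- cs >= 1L & cs <= w
  out[ok_r, ok_c] <- m[rs[ok_r], cs[ok_c]]
  out
}

#' Gray-level co-occurrence matrices
#'
#' Counts of co-occurring gray-level pairs at distance 1 along the four
#' in-plane directions (horizontal, vertical, both diagonals), optionally
#' symmetrized (pair counted in both orders). A direction with no valid
#' neighbour pairs degenerates to the diagonal gray-level histogram (each
#' pixel co-occurring with itself), so a single-pixel ROI yields the
#' single-entry matrix p(1,1) = 1.
#'
#' @param droi a [discretize()] result.
#' @param symmetric symmetrize each matrix.
#' @return list of `ng x ng` count matrices, one per direction.
#' @export
glcm_matrix <- function(droi, symmetric = TRUE) {
  ng <- droi$ng
  b <- droi$bins
  lapply(glcm_directions, function(d) {
    nb <- shift_mat(b, d[1], d[2])
    ok <- !is.na(b) & !is.na(nb)
    if (!any(ok)) {
      cnt <- diag(tabulate(b[!is.na(b)], nbins = ng), ng)
      if (symmetric) cnt <- cnt * 2
      return(cnt)
    }
    cnt <- matrix(tabulate((b[ok] - 1L) * ng + nb[ok], nbins = ng * ng),
                  ng, ng, byrow = TRUE)
    if (symmetric) cnt <- cnt + t(cnt)
    cnt
  })
}

glcm_features_one <- function(p) {
  ng <- nrow(p)
  i <- row(p); j <- col(p)
  px <- rowSums(p); py <- colSums(p)
  mu_x <- sum(seq_len(ng) * px); mu_y <- sum(seq_len(ng) * py)
  var_x <- sum((seq_len(ng) - mu_x)^2 * px)
  var_y <- sum((seq_len(ng) - mu_y)^2 * py)
  # p_{x+y}(k), k = 2..2Ng ; p_{x-y}(k), k = 0..Ng-1
  pxy_sum <- vapply(2:(2 * ng), function(k) sum(p[i + j == k]), numeric(1))
  k_sum <- 2:(2 * ng)
  pxy_diff <- vapply(0:(ng - 1), function(k) sum(p[abs(i - j) == k]),
                     numeric(1))
  k_diff <- 0:(ng - 1)
  ent <- function(q) { q <- q[q > 0]; -sum(q * log2(q)) }
  hxy <- ent(p)
  hx <- ent(px); hy <- ent(py)
  pp <- outer(px, py)
  okm <- p > 0 & pp > 0
  hxy1 <- -sum(p[okm] * log2(pp[okm]))
  hxy2 <- ent(pp)
  da <- sum(k_diff * pxy_diff)
  occ <- which(px > 0)
  mcc <- if (length(occ) < 2L) 1 else {
    a <- p[occ, occ, drop = FALSE]
    q <- diag(1 / px[occ], length(occ)) %*% a %*%
      diag(1 / py[occ], length(occ)) %*% t(a)
    ev <- sort(Re(eigen(q, only.values = TRUE)$values), decreasing = TRUE)
    sqrt(max(ev[2], 0))
  }
  corr <- if (var_x > 0 && var_y > 0)
    (sum(p * i * j) - mu_x * mu_y) / sqrt(var_x * var_y) else 1
  imc1 <- if (max(hx, hy) > 0) (hxy - hxy1) / max(hx, hy) else 0
  imc2 <- sqrt(max(0, 1 - exp(-2 * (hxy2 - hxy))))
  c(
    Autocorrelation = sum(p * i * j),
    ClusterProminence = sum(p * (i + j - mu_x - mu_y)^4),
    ClusterShade = sum(p * (i + j - mu_x - mu_y)^3),
    ClusterTendency = sum(p * (i + j - mu_x - mu_y)^2),
    Contrast = sum(p * (i - j)^2),
    Correlation = corr,
    DifferenceAverage = da,
    DifferenceEntropy = ent(pxy_diff),
    DifferenceVariance = sum(pxy_diff * (k_diff - da)^2),
    Id = sum(pxy_diff / (1 + k_diff)),
    Idm = sum(pxy_diff / (1 + k_diff^2)),
    Idmn = sum(pxy_diff / (1 + (k_diff / ng)^2)),
    Idn = sum(pxy_diff / (1 + k_diff / ng)),
    Imc1 = imc1,
    Imc2 = imc2,
    InverseVariance = sum(pxy_diff[-1] / k_diff[-1]^2),
    JointAverage = mu_x,
    JointEnergy = sum(p^2),
    JointEntropy = hxy,
    MCC = mcc,
    MaximumProbability = max(p),
    SumAverage = sum(k_sum * pxy_sum),
    SumEntropy = ent(pxy_sum),
    SumSquares = sum(p * (i - mu_x)^2)
  )
}

#' GLCM features
#'
#' The 24 standardized co-occurrence features, computed per direction on
#' the normalized (symmetrized) matrix and averaged over the four
#' directions.
#'
#' @inheritParams glcm_matrix
#' @return named numeric vector of 24 features.
#' @export
glcm_features <- function(droi, symmetric = TRUE) {
  mats <- glcm_matrix(droi, symmetric)
  per_dir <- vapply(mats, function(cnt) glcm_features_one(cnt / sum(cnt)),
                    numeric(24))
  rowMeans(per_dir)
}

# runs of equal gray level along the 4 directions; NA (out of mask) breaks
# runs. Returns counts matrix P[level, run length].
glrlm_matrix <- function(droi) {
  b <- droi$bins
  ng <- droi$ng
  lines_by <- list(
    row(b),                 # horizontal runs
    col(b),                 # vertical
    col(b) - row(b),        # diagonal
    col(b) + row(b)         # anti-diagonal
  )
  lapply(lines_by, function(f) {
    maxlen <- max(dim(b))
    cnt <- matrix(0, ng, maxlen)
    for (line in split(b, f)) {
      v <- line
      v[is.na(v)] <- -seq_len(sum(is.na(v)))  # break runs at gaps
      r <- rle(v)
      keep <- r$values > 0
      if (any(keep)) {
        idx <- cbind(r$values[keep], r$lengths[keep])
        for (k in seq_len(nrow(idx)))
          cnt[idx[k, 1], idx[k, 2]] <- cnt[idx[k, 1], idx[k, 2]] + 1
      }
    }
    cnt[, seq_len(max(1L, max_occupied_col(cnt))), drop = FALSE]
  })
}

max_occupied_col <- function(m) {
  nz <- which(colSums(m) > 0)
  if (length(nz) == 0L) 1L else max(nz)
}

# shared feature set for run-length (l = run length) and size-zone
# (l = zone size) matrices
rl_sz_features <- function(cnt, np, feature_names) {
  nr <- sum(cnt)
  i <- row(cnt); l <- col(cnt)
  p <- cnt / nr
  mu_i <- sum(p * i); mu_l <- sum(p * l)
  plog <- p[p > 0]
  f <- c(
    sum(cnt / l^2) / nr,                     # short emphasis
    sum(cnt * l^2) / nr,                     # long emphasis
    sum(rowSums(cnt)^2) / nr,                # gray-level non-uniformity
    sum(rowSums(cnt)^2) / nr^2,              # ... normalized
    sum(colSums(cnt)^2) / nr,                # run/zone non-uniformity
    sum(colSums(cnt)^2) / nr^2,              # ... normalized
    nr / np,                                 # percentage
    sum(p * (i - mu_i)^2),                   # gray-level variance
    sum(p * (l - mu_l)^2),                   # run/zone variance
    -sum(plog * log2(plog)),                 # entropy
    sum(cnt / i^2) / nr,                     # low gray-level emphasis
    sum(cnt * i^2) / nr,                     # high gray-level emphasis
    sum(cnt / (i^2 * l^2)) / nr,             # short + low
    sum(cnt * i^2 / l^2) / nr,               # short + high
    sum(cnt * l^2 / i^2) / nr,               # long + low
    sum(cnt * i^2 * l^2) / nr                # long + high
  )
  names(f) <- feature_names
  f
}

#' GLRLM features
#'
#' The 16 standardized run-length features, computed per direction
#' (horizontal, vertical, both diagonals; out-of-mask gaps break runs) and
#' averaged.
#'
#' @param droi a [discretize()] result.
#' @return named numeric vector of 16 features.
#' @export
glrlm_features <- function(droi) {
  np <- sum(droi$mask)
  nms <- c("ShortRunEmphasis", "LongRunEmphasis", "GrayLevelNonUniformity",
           "GrayLevelNonUniformityNormalized", "RunLengthNonUniformity",
           "RunLengthNonUniformityNormalized", "RunPercentage",
           "GrayLevelVariance", "RunVariance", "RunEntropy",
           "LowGrayLevelRunEmphasis", "HighGrayLevelRunEmphasis",
           "ShortRunLowGrayLevelEmphasis", "ShortRunHighGrayLevelEmphasis",
           "LongRunLowGrayLevelEmphasis", "LongRunHighGrayLevelEmphasis")
  per_dir <- vapply(glrlm_matrix(droi),
                    function(cnt) rl_sz_features(cnt, np, nms),
                    numeric(16))
  rowMeans(per_dir)
}

# 8-connected component labelling of a logical matrix (iterative BFS)
label_components8 <- function(bw) {
  h <- nrow(bw); w <- ncol(bw)
  lab <- matrix(0L, h, w)
  cur <- 0L
  todo <- which(bw)
  for (start in todo) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    stack <- start
    lab[start] <- cur
    while (length(stack) > 0L) {
      px <- stack[length(stack)]
      stack <- stack[-length(stack)]
      r <- (px - 1L) %% h + 1L
      c0 <- (px - 1L) %/% h + 1L
      for (dr in -1:1) for (dc in -1:1) {
        if (dr == 0L && dc == 0L) next
        rr <- r + dr; cc <- c0 + dc
        if (rr < 1L || rr > h || cc < 1L || cc > w) next
        q <- (cc - 1L) * h + rr
        if (bw[q] && lab[q] == 0L) {
          lab[q] <- cur
          stack <- c(stack, q)
        }
      }
    }
  }
  list(labels = lab, n = cur)
}

#' GLSZM zone table and features
#'
#' Zones are 8-connected components of equal gray level within the mask.
#' `glszm_matrix` returns the `ng x max-zone-size` count matrix;
#' `glszm_features` the 16 standardized size-zone features.
#'
#' @param droi a [discretize()] result.
#' @return `glszm_matrix`: numeric count matrix; `glszm_features`: named
#'   numeric vector of 16 features.
#' @export
glszm_matrix <- function(droi) {
  b <- droi$bins
  ng <- droi$ng
  zones <- list()
  for (lev in sort(unique(b[!is.na(b)]))) {
    comp <- label_components8(!is.na(b) & b == lev)
    if (comp$n > 0)
      zones[[length(zones) + 1L]] <-
        cbind(lev, tabulate(comp$labels[comp$labels > 0], nbins = comp$n))
  }
  zl <- do.call(rbind, zones)
  cnt <- matrix(0, ng, max(zl[, 2]))
  for (k in seq_len(nrow(zl)))
    cnt[zl[k, 1], zl[k, 2]] <- cnt[zl[k, 1], zl[k, 2]] + 1
  cnt
}

#' @rdname glszm_matrix
#' @export
glszm_features <- function(droi) {
  np <- sum(droi$mask)
  nms <- c("SmallAreaEmphasis", "LargeAreaEmphasis", "GrayLevelNonUniformity",
           "GrayLevelNonUniformityNormalized", "SizeZoneNonUniformity",
           "SizeZoneNonUniformityNormalized", "ZonePercentage",
           "GrayLevelVariance", "ZoneVariance", "ZoneEntropy",
           "LowGrayLevelZoneEmphasis", "HighGrayLevelZoneEmphasis",
           "SmallAreaLowGrayLevelEmphasis", "SmallAreaHighGrayLevelEmphasis",
           "LargeAreaLowGrayLevelEmphasis", "LargeAreaHighGrayLevelEmphasis")
  rl_sz_features(glszm_matrix(droi), np, nms)
}

#' GLDM dependence matrix and features
#'
#' For each in-mask pixel the dependence count is the number of its in-mask
#' 8-neighbours whose gray level differs by at most `alpha` (default 0,
#' exact-level dependence). The matrix indexes gray level against
#' dependence size `j = count + 1` (the centre pixel counts as part of its
#' own dependence group), so the small-dependence emphases are defined for
#' isolated pixels.
#'
#' @param droi a [discretize()] result.
#' @param alpha gray-level tolerance.
#' @return `gldm_matrix`: count matrix (`ng` rows, 9 columns for j=1..9);
#'   `gldm_features`: named numeric vector of 14 features.
#' @export
gldm_matrix <- function(droi, alpha = 0L) {
  b <- droi$bins
  ng <- droi$ng
  dep <- matrix(0L, nrow(b), ncol(b))
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0L && dc == 0L) next
    nb <- shift_mat(b, dr, dc)
    dep <- dep + (!is.na(nb) & !is.na(b) & abs(nb - b) <= alpha)
  }
  ok <- !is.na(b)
  cnt <- matrix(tabulate((b[ok] - 1L) * 9L + dep[ok] + 1L, nbins = ng * 9L),
                ng, 9L, byrow = TRUE)
  cnt
}

#' @rdname gldm_matrix
#' @export
gldm_features <- function(droi, alpha = 0L) {
  cnt <- gldm_matrix(droi, alpha)
  nz <- sum(cnt)
  i <- row(cnt); j <- col(cnt)
  p <- cnt / nz
  mu_i <- sum(p * i); mu_j <- sum(p * j)
  plog <- p[p > 0]
  c(
    SmallDependenceEmphasis = sum(cnt / j^2) / nz,
    LargeDependenceEmphasis = sum(cnt * j^2) / nz,
    GrayLevelNonUniformity = sum(rowSums(cnt)^2) / nz,
    DependenceNonUniformity = sum(colSums(cnt)^2) / nz,
    DependenceNonUniformityNormalized = sum(colSums(cnt)^2) / nz^2,
    GrayLevelVariance = sum(p * (i - mu_i)^2),
    DependenceVariance = sum(p * (j - mu_j)^2),
    DependenceEntropy = -sum(plog * log2(plog)),
    LowGrayLevelEmphasis = sum(cnt / i^2) / nz,
    HighGrayLevelEmphasis = sum(cnt * i^2) / nz,
    SmallDependenceLowGrayLevelEmphasis = sum(cnt / (i^2 * j^2)) / nz,
    SmallDependenceHighGrayLevelEmphasis = sum(cnt * i^2 / j^2) / nz,
    LargeDependenceLowGrayLevelEmphasis = sum(cnt * j^2 / i^2) / nz,
    LargeDependenceHighGrayLevelEmphasis = sum(cnt * i^2 * j^2) / nz
  )
}

#' NGTDM table and features
#'
#' For every in-mask pixel with at least one in-mask 8-neighbour, the
#' absolute difference between its gray level and the mean gray level of
#' those neighbours is accumulated per level (`s_i`); `n_i` counts the
#' contributing pixels. The five neighbourhood gray-tone difference
#' features derive from these sums. Strength uses a 1e-16 guard in its
#' denominator so constant ROIs return 0 rather than 0/0.
#'
#' @param droi a [discretize()] result.
#' @return `ngtdm_table`: data.frame with columns `level`, `n`, `p`, `s`;
#'   `ngtdm_features`: named numeric vector of 5 features.
#' @export
ngtdm_table <- function(droi) {
  b <- droi$bins
  nbr_sum <- matrix(0, nrow(b), ncol(b))
  nbr_n <- matrix(0L, nrow(b), ncol(b))
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0L && dc == 0L) next
    nb <- shift_mat(b, dr, dc)
    valid <- !is.na(nb)
    nbr_sum[valid] <- nbr_sum[valid] + nb[valid]
    nbr_n <- nbr_n + valid
  }
  ok <- !is.na(b) & nbr_n > 0L
  lev <- b[ok]
  diffs <- abs(lev - nbr_sum[ok] / nbr_n[ok])
  levels <- sort(unique(lev))
  n_i <- vapply(levels, function(l) sum(lev == l), numeric(1))
  s_i <- vapply(levels, function(l) sum(diffs[lev == l]), numeric(1))
  data.frame(level = levels, n = n_i, p = n_i / sum(n_i), s = s_i)
}

#' @rdname ngtdm_table
#' @export
ngtdm_features <- function(droi) {
  tb <- ngtdm_table(droi)
  nvp <- sum(tb$n)
  ngp <- nrow(tb)
  i <- tb$level; p <- tb$p; s <- tb$s
  dif2 <- outer(i, i, function(a, b) (a - b)^2)
  psum <- outer(p, p, "+")
  coarse_den <- sum(p * s)
  coarseness <- if (coarse_den > 0) 1 / coarse_den else 1e6
  contrast <- if (ngp > 1)
    sum(outer(p, p) * dif2) / (ngp * (ngp - 1)) * sum(s) / nvp else 0
  ip <- i * p
  busy_den <- sum(abs(outer(ip, ip, "-")))
  busyness <- if (busy_den > 0) coarse_den / busy_den else 0
  ps <- p * s
  complexity <- sum(abs(outer(i, i, "-")) * outer(ps, ps, "+") /
                      outer(p, p, "+")) / nvp
  strength <- sum(psum * dif2) / (1e-16 + sum(s))
  c(Coarseness = coarseness, Contrast = contrast, Busyness = busyness,
    Complexity = complexity, Strength = strength)
}
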