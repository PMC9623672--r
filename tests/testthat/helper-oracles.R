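# Independent brute-force oracles. These re-derive every texture matrix,
# first-order statistic and window map by direct enumeration (scalar loops,
# no shared code with the package internals) so the vectorized
# implementations can be checked against them.

# random discretized ROI on a random mask
random_droi <- function(seed, max_side = 10L, levels = 2:5) {
  set.seed(seed)
  h <- sample(3:max_side, 1); w <- sample(3:max_side, 1)
  ng <- sample(levels, 1)
  vals <- matrix(sample(seq_len(ng), h * w, replace = TRUE), h, w)
  mask <- matrix(stats::runif(h * w) < 0.8, h, w)
  if (!any(mask)) mask[1, 1] <- TRUE
  # ensure level 1 occurs in-mask so min-anchored binning keeps the levels
  vals[which(mask)[1]] <- 1L
  list(vals = vals, mask = mask,
       droi = discretize(vals * 0.1, mask, bin_width = 0.1))
}

in_bounds <- function(r, c, h, w) r >= 1 && r <= h && c >= 1 && c <= w

oracle_glcm <- function(bins, dr, dc, ng, symmetric = TRUE) {
  h <- nrow(bins); w <- ncol(bins)
  m <- matrix(0, ng, ng)
  for (r in seq_len(h)) for (c in seq_len(w)) {
    if (is.na(bins[r, c])) next
    r2 <- r + dr; c2 <- c + dc
    if (!in_bounds(r2, c2, h, w) || is.na(bins[r2, c2])) next
    m[bins[r, c], bins[r2, c2]] <- m[bins[r, c], bins[r2, c2]] + 1
    if (symmetric)
      m[bins[r2, c2], bins[r, c]] <- m[bins[r2, c2], bins[r, c]] + 1
  }
  m
}

oracle_glrlm <- function(bins, dr, dc, ng, maxlen) {
  h <- nrow(bins); w <- ncol(bins)
  m <- matrix(0, ng, maxlen)
  prev_ok <- function(r, c) {
    rp <- r - dr; cp <- c - dc
    in_bounds(rp, cp, h, w) && !is.na(bins[rp, cp]) &&
      bins[rp, cp] == bins[r, c]
  }
  for (r in seq_len(h)) for (c in seq_len(w)) {
    if (is.na(bins[r, c]) || prev_ok(r, c)) next   # only run starts
    len <- 1L
    r2 <- r + dr; c2 <- c + dc
    while (in_bounds(r2, c2, h, w) && !is.na(bins[r2, c2]) &&
           bins[r2, c2] == bins[r, c]) {
      len <- len + 1L; r2 <- r2 + dr; c2 <- c2 + dc
    }
    m[bins[r, c], len] <- m[bins[r, c], len] + 1
  }
  m
}

# 8-connected zones by repeated boolean dilation (independent of the
# package's stack-based labelling)
oracle_zone_sizes <- function(bins, level) {
  bw <- !is.na(bins) & bins == level
  sizes <- integer(0)
  while (any(bw)) {
    seed <- matrix(FALSE, nrow(bw), ncol(bw))
    seed[which(bw)[1]] <- TRUE
    repeat {
      grown <- seed
      idx <- which(seed, arr.ind = TRUE)
      for (k in seq_len(nrow(idx))) {
        for (dr in -1:1) for (dc in -1:1) {
          r <- idx[k, 1] + dr; c <- idx[k, 2] + dc
          if (in_bounds(r, c, nrow(bw), ncol(bw)) && bw[r, c])
            grown[r, c] <- TRUE
        }
      }
      if (identical(grown, seed)) break
      seed <- grown
    }
    sizes <- c(sizes, sum(seed))
    bw <- bw & !seed
  }
  sizes
}

oracle_glszm <- function(bins, ng) {
  max_size <- sum(!is.na(bins))
  m <- matrix(0, ng, max_size)
  for (lev in seq_len(ng)) {
    for (s in oracle_zone_sizes(bins, lev)) m[lev, s] <- m[lev, s] + 1
  }
  occupied <- which(colSums(m) > 0)
  m[, seq_len(max(occupied, 1)), drop = FALSE]
}

oracle_gldm <- function(bins, ng, alpha = 0) {
  h <- nrow(bins); w <- ncol(bins)
  m <- matrix(0, ng, 9)
  for (r in seq_len(h)) for (c in seq_len(w)) {
    if (is.na(bins[r, c])) next
    dep <- 0L
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      r2 <- r + dr; c2 <- c + dc
      if (in_bounds(r2, c2, h, w) && !is.na(bins[r2, c2]) &&
          abs(bins[r2, c2] - bins[r, c]) <= alpha)
        dep <- dep + 1L
    }
    m[bins[r, c], dep + 1L] <- m[bins[r, c], dep + 1L] + 1
  }
  m
}

oracle_ngtdm <- function(bins, ng) {
  h <- nrow(bins); w <- ncol(bins)
  n_i <- numeric(ng); s_i <- numeric(ng)
  for (r in seq_len(h)) for (c in seq_len(w)) {
    if (is.na(bins[r, c])) next
    nbrs <- c()
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      r2 <- r + dr; c2 <- c + dc
      if (in_bounds(r2, c2, h, w) && !is.na(bins[r2, c2]))
        nbrs <- c(nbrs, bins[r2, c2])
    }
    if (length(nbrs) == 0) next
    lev <- bins[r, c]
    n_i[lev] <- n_i[lev] + 1
    s_i[lev] <- s_i[lev] + abs(lev - mean(nbrs))
  }
  list(n = n_i, s = s_i)
}

# first-order statistics recomputed with naive per-formula loops
oracle_first_order <- function(x, bins_in_mask) {
  n <- length(x)
  mu <- sum(x) / n
  m2 <- sum((x - mu)^2) / n
  m3 <- sum((x - mu)^3) / n
  m4 <- sum((x - mu)^4) / n
  counts <- table(bins_in_mask)
  p <- as.numeric(counts) / n
  q <- unname(stats::quantile(x, c(.10, .25, .50, .75, .90), type = 7))
  mid <- x[x >= q[1] & x <= q[5]]
  c(Energy = sum(x^2), TotalEnergy = sum(x^2),
    Entropy = -sum(p * log2(p)), Minimum = min(x),
    `10Percentile` = q[1], `90Percentile` = q[5], Maximum = max(x),
    Mean = mu, Median = q[3], InterquartileRange = q[4] - q[2],
    Range = max(x) - min(x),
    MeanAbsoluteDeviation = sum(abs(x - mu)) / n,
    RobustMeanAbsoluteDeviation = sum(abs(mid - mean(mid))) / length(mid),
    RootMeanSquared = sqrt(sum(x^2) / n),
    Skewness = if (m2 > 0) m3 / m2^1.5 else 0,
    Kurtosis = if (m2 > 0) m4 / m2^2 else 0,
    Variance = m2, Uniformity = sum(p^2))
}

# naive sliding-window recomputation of a local feature map value
oracle_window_stat <- function(v, mask, r, c, window, feature,
                               min_pixels = 4, bin_width = 0.1) {
  a <- (window - 1) %/% 2; b <- window %/% 2
  rs <- max(1, r - a):min(nrow(v), r + b)
  cs <- max(1, c - a):min(ncol(v), c + b)
  sel <- mask[rs, cs]
  if (!mask[r, c] || sum(sel) < min_pixels) return(NA_real_)
  x <- v[rs, cs][sel]
  if (feature == "mean") return(mean(x))
  if (feature == "skewness") {
    m2 <- mean((x - mean(x))^2)
    if (m2 <= 1e-12) return(0)
    return(mean((x - mean(x))^3) / m2^1.5)
  }
  if (feature == "entropy") {
    bins <- floor((x - min(x)) / bin_width + 1e-9)
    p <- as.numeric(table(bins)) / length(x)
    return(-sum(p * log2(p)))
  }
  stop("unsupported feature in oracle")
}

# scalar crossing-number point-in-polygon (with boundary test), written
# independently of the package's vectorized version
oracle_point_in_polygon <- function(pr, pc, verts) {
  n <- nrow(verts)
  crossings <- 0
  for (k in seq_len(n)) {
    j <- if (k == 1) n else k - 1
    r1 <- verts[k, 1]; c1 <- verts[k, 2]
    r2 <- verts[j, 1]; c2 <- verts[j, 2]
    # boundary?
    d <- abs((pc - c1) * (r2 - r1) - (pr - r1) * (c2 - c1))
    len <- sqrt((r2 - r1)^2 + (c2 - c1)^2)
    if (len > 0 && d / len < 1e-9 &&
        pr >= min(r1, r2) - 1e-9 && pr <= max(r1, r2) + 1e-9 &&
        pc >= min(c1, c2) - 1e-9 && pc <= max(c1, c2) + 1e-9)
      return(TRUE)
    if ((r1 > pr) != (r2 > pr)) {
      x_int <- (c2 - c1) * (pr - r1) / (r2 - r1) + c1
      if (pc < x_int) crossings <- crossings + 1
    }
  }
  crossings %% 2 == 1
}

# separable convolution oracle for the stationary Haar low-pass
oracle_haar_ll <- function(v) {
  h <- nrow(v); w <- ncol(v)
  out <- matrix(0, h, w)
  for (r in seq_len(h)) for (c in seq_len(w)) {
    rn <- min(r + 1, h); cn <- min(c + 1, w)
    out[r, c] <- (v[r, c] + v[rn, c] + v[r, cn] + v[rn, cn]) / 2
  }
  out
}
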