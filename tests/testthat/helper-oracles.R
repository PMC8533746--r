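# Independent brute-force reference implementations used as oracles.
# These deliberately share no code with the package internals.

# full 2-D convolution with zero padding, explicit quadruple loop
bruteConv2 <- function(img, kernel) {
  h <- (nrow(kernel) - 1) / 2
  out <- matrix(0, nrow(img), ncol(img))
  for (i in seq_len(nrow(img))) {
    for (j in seq_len(ncol(img))) {
      acc <- 0
      for (a in -h:h) {
        for (b in -h:h) {
          ii <- i - a; jj <- j - b
          v <- if (ii >= 1 && ii <= nrow(img) && jj >= 1 && jj <= ncol(img)) {
            img[ii, jj]
          } else 0
          acc <- acc + kernel[a + h + 1, b + h + 1] * v
        }
      }
      out[i, j] <- acc
    }
  }
  out
}

# sampled 2-D Gaussian kernel, truncated at 4 sigma, normalized
bruteGaussKernel <- function(sigma) {
  h <- ceiling(4 * sigma)
  k1 <- exp(-((-h):h)^2 / (2 * sigma^2))
  k1 <- k1 / sum(k1)
  outer(k1, k1)
}

# intensity-weighted centroid by explicit loop; pixel i center at (i - 0.5) * s
bruteCentroid <- function(g, pixelSize = 1, origin = c(0, 0)) {
  sx <- 0; sy <- 0; tot <- 0
  for (i in seq_len(nrow(g))) {
    for (j in seq_len(ncol(g))) {
      sx <- sx + g[i, j] * (origin[1] + (i - 0.5) * pixelSize)
      sy <- sy + g[i, j] * (origin[2] + (j - 0.5) * pixelSize)
      tot <- tot + g[i, j]
    }
  }
  c(sx / tot, sy / tot)
}

# 2-D histogram by explicit per-point loop
bruteBin <- function(x, y, xlim, ylim, s, nx, ny) {
  g <- matrix(0, nx, ny)
  for (k in seq_along(x)) {
    i <- floor((x[k] - xlim[1]) / s) + 1
    j <- floor((y[k] - ylim[1]) / s) + 1
    if (i >= 1 && i <= nx && j >= 1 && j <= ny) g[i, j] <- g[i, j] + 1
  }
  g
}

# pixel-by-pixel evaluation of the mutual-intensity colocalization rule
bruteColoc <- function(a, b, tA, tB, rho) {
  out <- matrix(FALSE, nrow(a), ncol(a))
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(ncol(a))) {
      lo <- min(a[i, j], b[i, j]); hi <- max(a[i, j], b[i, j])
      r <- if (hi > 0) lo / hi else 0
      out[i, j] <- a[i, j] >= tA && b[i, j] >= tB && r >= rho
    }
  }
  out
}

# connected-component labeling by breadth-first flood fill
bruteLabel <- function(mask, connectivity) {
  m <- mask > 0
  lab <- matrix(0L, nrow(m), ncol(m))
  nb <- if (connectivity == 4) {
    rbind(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))
  } else {
    as.matrix(expand.grid(-1:1, -1:1))[-5, ]
  }
  cur <- 0L
  for (i in seq_len(nrow(m))) {
    for (j in seq_len(ncol(m))) {
      if (m[i, j] && lab[i, j] == 0L) {
        cur <- cur + 1L
        queue <- list(c(i, j))
        lab[i, j] <- cur
        while (length(queue)) {
          p <- queue[[1]]; queue <- queue[-1]
          for (k in seq_len(nrow(nb))) {
            q <- p + nb[k, ]
            if (q[1] >= 1 && q[1] <= nrow(m) && q[2] >= 1 && q[2] <= ncol(m) &&
                m[q[1], q[2]] && lab[q[1], q[2]] == 0L) {
              lab[q[1], q[2]] <- cur
              queue <- c(queue, list(q))
            }
          }
        }
      }
    }
  }
  lab
}

# label matrices agree up to renumbering
sameLabeling <- function(a, b) {
  if (!identical(a > 0, b > 0)) return(FALSE)
  fg <- a > 0
  length(unique(paste(a[fg], b[fg]))) == length(unique(a[fg])) &&
    max(a) == max(b)
}

# isotropic Gaussian sigma fitted to an impulse response by log-quadratic
# least squares (the response of a sampled-Gaussian filter is exactly
# log-quadratic in the squared radius)
fitImpulseSigma <- function(resp, center) {
  idx <- which(resp > max(resp) * 1e-6, arr.ind = TRUE)
  r2 <- (idx[, 1] - center[1])^2 + (idx[, 2] - center[2])^2
  v <- log(resp[idx])
  slope <- stats::coef(stats::lm(v ~ r2))[["r2"]]
  sqrt(-1 / (2 * slope))
}

fiveClasses <- c(
  "IN_CLEFT", "NEAR_CLEFT", "PRE_PREFERENTIAL", "POST_PREFERENTIAL", "ABSENT"
)
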