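# Fixture builders and independent oracles used across the suite.

# 2-D Gaussian spot image (y rows, x cols); centers is an n x 2 matrix of
# (y, x); supports anisotropic sigma = c(sy, sx).
gaussian_image <- function(ny, nx, centers, sigma, amplitude = 1,
                           background = 0) {
  if (length(sigma) == 1L) sigma <- c(sigma, sigma)
  img <- matrix(background, ny, nx)
  yy <- row(img); xx <- col(img)
  centers <- matrix(centers, ncol = 2L)
  for (i in seq_len(nrow(centers))) {
    img <- img + amplitude *
      exp(-((yy - centers[i, 1])^2 / (2 * sigma[1]^2) +
              (xx - centers[i, 2])^2 / (2 * sigma[2]^2)))
  }
  img
}

# --- brute-force find-maxima oracle -------------------------------------
# Exhaustive prominence computation for small images with no tied values
# (other than plateaus, which the random fixtures avoid by jittering).
# For each local maximum p: the highest saddle is the largest threshold t
# at which p is 8-connected, within the mask, to a strictly higher pixel;
# prominence = value(p) - saddle. A maximum with no higher pixel in its
# mask component is referenced to that component's minimum.
oracle_find_maxima <- function(image, mask, tol) {
  nr <- nrow(image); nc <- ncol(image)
  is_local_max <- function(r, c) {
    v <- image[r, c]
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      rr <- r + dr; cc <- c + dc
      if (rr < 1 || rr > nr || cc < 1 || cc > nc || !mask[rr, cc]) next
      if (image[rr, cc] >= v) return(FALSE)
    }
    TRUE
  }
  # flood the component of (r, c) restricted to mask & image >= t
  flood <- function(r, c, t) {
    seen <- matrix(FALSE, nr, nc)
    queue <- list(c(r, c))
    seen[r, c] <- TRUE
    comp <- list()
    while (length(queue) > 0) {
      p <- queue[[length(queue)]]; queue[[length(queue)]] <- NULL
      comp[[length(comp) + 1]] <- p
      for (dr in -1:1) for (dc in -1:1) {
        rr <- p[1] + dr; cc <- p[2] + dc
        if (rr < 1 || rr > nr || cc < 1 || cc > nc) next
        if (seen[rr, cc] || !mask[rr, cc] || image[rr, cc] < t) next
        seen[rr, cc] <- TRUE
        queue[[length(queue) + 1]] <- c(rr, cc)
      }
    }
    do.call(rbind, comp)
  }
  lm_flag <- matrix(vapply(seq_len(nr * nc), function(i) {
    r <- ((i - 1) %% nr) + 1; c <- ((i - 1) %/% nr) + 1
    mask[r, c] && is_local_max(r, c)
  }, logical(1)), nr, nc)
  cand <- which(lm_flag)
  out <- NULL
  levels <- sort(unique(image[mask]))
  for (i in cand) {
    r <- ((i - 1) %% nr) + 1; c <- ((i - 1) %/% nr) + 1
    v <- image[r, c]
    # binary search the highest level at which p connects to higher ground
    lo <- 1L; hi <- length(levels); saddle <- NA_real_
    connects <- function(t) {
      comp <- flood(r, c, t)
      any(image[comp] > v)
    }
    if (connects(levels[1L])) {
      while (lo < hi) {
        mid <- (lo + hi + 1L) %/% 2L
        if (connects(levels[mid])) lo <- mid else hi <- mid - 1L
      }
      saddle <- levels[lo]
    } else {
      saddle <- min(image[flood(r, c, levels[1L])])
    }
    prom <- v - saddle
    if (prom > tol)
      out <- rbind(out, c(y = r, x = c, value = v, prominence = prom))
  }
  if (is.null(out))
    return(data.frame(y = integer(0), x = integer(0),
                      value = numeric(0), prominence = numeric(0)))
  out <- as.data.frame(out)
  out[order(-out$value), , drop = FALSE]
}

# --- exact Wilcoxon oracles ---------------------------------------------
# Signed-rank: enumerate all 2^n sign assignments (requires no zeros and
# no tied absolute values).
oracle_signed_rank_p <- function(d) {
  n <- length(d)
  rk <- rank(abs(d))
  V <- sum(rk[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  Vs <- signs %*% rk
  pl <- mean(Vs <= V); pu <- mean(Vs >= V)
  min(1, 2 * min(pl, pu))
}

# Rank-sum: enumerate all choose(m+n, m) group assignments.
oracle_rank_sum_p <- function(a, b) {
  m <- length(a)
  pooled <- c(a, b)
  rk <- rank(pooled)
  W <- sum(rk[seq_len(m)]) - m * (m + 1) / 2
  idx <- utils::combn(length(pooled), m)
  Ws <- apply(idx, 2, function(ii) sum(rk[ii]) - m * (m + 1) / 2)
  pl <- mean(Ws <= W); pu <- mean(Ws >= W)
  min(1, 2 * min(pl, pu))
}

# random valid rate set with log-uniform rates
random_rate_set <- function(lo = 1e-3, hi = 10) {
  r <- 10 ^ stats::runif(4, log10(lo), log10(hi))
  rate_set(r[1], r[2], r[3], r[4])
}
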