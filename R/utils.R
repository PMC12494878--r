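#' @importFrom methods new validObject is slot
#' @importFrom stats quantile rnorm rlnorm runif rbinom plogis lm coef
#'   p.adjust t.test approx hclust as.dist sd setNames aggregate median
#'   pchisq qnorm cor complete.cases
#' @importFrom utils head tail write.csv read.csv packageVersion
NULL

# --- seeding ------------------------------------------------------------

#' Derive a child seed from a global seed and an operation tag
#'
#' A single global integer seed fans out to per-operation seeds by a fixed
#' arithmetic derivation so partial pipeline reruns are stable: the tag is
#' hashed by a small polynomial over its UTF-8 bytes and combined with the
#' parent seed modulo 2^31 - 1.
#'
#' @param seed integer parent seed.
#' @param tag character scalar naming the operation ("field", "growth", ...).
#' @return an integer seed in [1, 2^31 - 2], deterministic in (seed, tag).
#' @export
#' @examples
#' childSeed(1L, "field")
childSeed <- function(seed, tag) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(tag))
  m <- 2147483647  # 2^31 - 1, keeps results in 32-bit integer range
  h <- 0
  for (b in utf8ToInt(tag)) h <- (h * 131 + b) %% m
  as.integer(1 + (abs(as.numeric(seed)) * 48271 + h * 16807) %% (m - 1))
}

# Evaluate `expr` under `seed` without disturbing the caller's RNG stream.
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

# --- binomial intervals -------------------------------------------------

#' Wilson score interval for a binomial proportion
#'
#' Used for the 95% error bars on per-bin foci fractions; well behaved at
#' observed fractions of 0 and 1, unlike the normal approximation (which is
#' available via \code{method = "normal"}).
#'
#' @param k number of successes.
#' @param n number of trials (> 0).
#' @param conf confidence level, default 0.95.
#' @param method "wilson" (default) or "normal".
#' @return named numeric vector with elements \code{fraction}, \code{lo},
#'   \code{hi}.
#' @export
#' @examples
#' wilsonInterval(3, 10)
wilsonInterval <- function(k, n, conf = 0.95, method = c("wilson", "normal")) {
  method <- match.arg(method)
  stopifnot(n > 0, k >= 0, k <= n)
  p <- k / n
  z <- qnorm(1 - (1 - conf) / 2)
  if (method == "wilson") {
    denom <- 1 + z^2 / n
    centre <- (p + z^2 / (2 * n)) / denom
    half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
    lo <- max(0, centre - half)
    hi <- min(1, centre + half)
  } else {
    half <- z * sqrt(p * (1 - p) / n)
    lo <- max(0, p - half)
    hi <- min(1, p + half)
  }
  c(fraction = p, lo = lo, hi = hi)
}

# --- connected components ----------------------------------------------

# Label connected components of a logical matrix by breadth-first search.
# `connectivity` is 4 (edge neighbours) or 8 (edge + diagonal). Labels are
# assigned in raster order of each component's first-encountered pixel, so
# the labelling is deterministic. Returns an integer matrix, 0 = background.
labelComponents <- function(mask, connectivity = 8) {
  stopifnot(is.matrix(mask), connectivity %in% c(4, 8))
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  if (!any(mask)) return(lab)
  dr <- c(-1L, 1L, 0L, 0L); dc <- c(0L, 0L, -1L, 1L)
  if (connectivity == 8) {
    dr <- c(dr, -1L, -1L, 1L, 1L); dc <- c(dc, -1L, 1L, -1L, 1L)
  }
  nextLab <- 0L
  # raster order: along rows first (row-major), so ties downstream are stable
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    if (!mask[r, c] || lab[r, c] > 0L) next
    nextLab <- nextLab + 1L
    queue <- matrix(c(r, c), ncol = 2)
    lab[r, c] <- nextLab
    while (nrow(queue) > 0L) {
      cur <- queue[1L, , drop = FALSE]
      queue <- queue[-1L, , drop = FALSE]
      rr <- cur[1] + dr; cc <- cur[2] + dc
      ok <- rr >= 1L & rr <= nr & cc >= 1L & cc <= nc
      rr <- rr[ok]; cc <- cc[ok]
      idx <- cbind(rr, cc)
      hit <- mask[idx] & lab[idx] == 0L
      if (any(hit)) {
        idx <- idx[hit, , drop = FALSE]
        lab[idx] <- nextLab
        queue <- rbind(queue, idx)
      }
    }
  }
  lab
}

# --- perimeter & circularity --------------------------------------------

# Weighted border-crossing perimeter estimator on a logical matrix.
# Border pixels (those losing a 4-neighbour under erosion) are convolved
# with the kernel [[10,2,10],[2,1,2],[10,2,10]]; the resulting local codes
# map to step lengths of 1, sqrt(2) or (1+sqrt(2))/2. This is the standard
# estimator used across image-analysis toolkits; it tracks the true
# Euclidean boundary length far better than raw pixel-edge counting.
regionPerimeter <- function(mask) {
  stopifnot(is.matrix(mask))
  m <- matrix(0L, nrow(mask) + 2L, ncol(mask) + 2L)
  m[2:(nrow(mask) + 1L), 2:(ncol(mask) + 1L)] <- as.integer(mask)
  nr <- nrow(m); nc <- ncol(m)
  sh <- function(x, dr, dc) {  # shift with zero padding
    out <- matrix(0L, nr, nc)
    rs <- seq_len(nr) - dr; cs <- seq_len(nc) - dc
    okr <- rs >= 1L & rs <= nr; okc <- cs >= 1L & cs <= nc
    out[okr, okc] <- x[rs[okr], cs[okc]]
    out
  }
  # 4-connected erosion: pixel survives if all edge neighbours are set
  er <- m & sh(m, 1, 0) & sh(m, -1, 0) & sh(m, 0, 1) & sh(m, 0, -1)
  border <- m - as.integer(er)
  k <- rbind(c(10, 2, 10), c(2, 1, 2), c(10, 2, 10))
  conv <- matrix(0, nr, nc)
  for (dr in -1:1) for (dc in -1:1)
    conv <- conv + k[dr + 2, dc + 2] * sh(border, dr, dc)
  w <- numeric(50)
  w[c(5, 7, 15, 17, 25, 27) + 1] <- 1
  w[c(21, 33) + 1] <- sqrt(2)
  w[c(13, 23) + 1] <- (1 + sqrt(2)) / 2
  codes <- conv[border == 1L]
  sum(w[pmin(codes, 49) + 1])
}

# Circularity 4*pi*A/P^2 of a pixel region; 1 for a disc, lower for
# elongated shapes. Discrete-geometry overshoot slightly above 1 is possible
# for very small discs. Regions of 1-2 pixels (or estimator perimeter 0)
# are assigned 1.0 by convention.
regionCircularity <- function(mask) {
  a <- sum(mask)
  if (a <= 2) return(1.0)
  p <- regionPerimeter(mask)
  if (p <= 0) return(1.0)
  4 * pi * a / p^2
}

# trapezoid rule on (x, y)
trapz <- function(x, y) {
  n <- length(x)
  if (n < 2) stop("need at least two points to integrate")
  sum((y[-1] + y[-n]) / 2 * diff(x))
}
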