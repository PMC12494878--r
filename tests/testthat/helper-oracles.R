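# Independent reference implementations used as oracles. These deliberately
# share no code with the package: components are found by an explicit-stack
# flood fill over a double loop, and enrichment tails are enumerated.

# Brute-force puncta finder: scan every pixel, test both intensity
# conditions, flood-fill components, keep the largest (ties: lowest min
# row, then lowest min col). Returns a list keyed by cell id of sorted
# linear pixel indices, or NULL when a cell has no candidate pixel.
punctaOracle <- function(image, mask, background, foldThr = 2.5,
                         marginAU = 100, connectivity = 8) {
  nr <- nrow(image); nc <- ncol(image)
  out <- list()
  for (lb in setdiff(sort(unique(as.vector(mask))), 0L)) {
    vals <- c()
    for (r in 1:nr) for (c in 1:nc)
      if (mask[r, c] == lb) vals <- c(vals, image[r, c])
    med <- median(vals)
    thr <- max(foldThr * med, background + marginAU)
    cand <- matrix(FALSE, nr, nc)
    for (r in 1:nr) for (c in 1:nc)
      cand[r, c] <- mask[r, c] == lb && image[r, c] >= thr
    if (!any(cand)) next
    seen <- matrix(FALSE, nr, nc)
    comps <- list()
    for (r in 1:nr) for (c in 1:nc) {
      if (!cand[r, c] || seen[r, c]) next
      stack <- list(c(r, c)); seen[r, c] <- TRUE
      pix <- matrix(numeric(0), ncol = 2)
      while (length(stack)) {
        p <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
        pix <- rbind(pix, p)
        for (dr in -1:1) for (dc in -1:1) {
          if (dr == 0 && dc == 0) next
          if (connectivity == 4 && abs(dr) + abs(dc) == 2) next
          rr <- p[1] + dr; cc <- p[2] + dc
          if (rr >= 1 && rr <= nr && cc >= 1 && cc <= nc &&
              cand[rr, cc] && !seen[rr, cc]) {
            seen[rr, cc] <- TRUE
            stack[[length(stack) + 1]] <- c(rr, cc)
          }
        }
      }
      comps[[length(comps) + 1]] <- pix
    }
    sizes <- vapply(comps, nrow, integer(1))
    cand2 <- which(sizes == max(sizes))
    if (length(cand2) > 1) {
      keys <- t(vapply(cand2, function(i)
        c(min(comps[[i]][, 1]), min(comps[[i]][, 2])), numeric(2)))
      cand2 <- cand2[order(keys[, 1], keys[, 2])[1]]
    }
    pix <- comps[[cand2]]
    out[[as.character(lb)]] <- sort(as.numeric((pix[, 2] - 1) * nr +
                                                 pix[, 1]))
  }
  out
}

# Random small labelled image with integer intensities (ties on purpose):
# a few rectangular cells, each with 0-2 bright blobs.
randomQuantImage <- function(seed) {
  set.seed(seed)
  nr <- sample(24:64, 1); nc <- sample(24:64, 1)
  bg <- sample(50:300, 1)
  img <- matrix(bg + sample(0:20, nr * nc, TRUE), nr, nc)
  mask <- matrix(0L, nr, nc)
  nCell <- sample(1:3, 1)
  for (i in seq_len(nCell)) {
    for (try in 1:20) {
      h <- sample(8:14, 1); w <- sample(8:14, 1)
      r0 <- sample(1:(nr - h), 1); c0 <- sample(1:(nc - w), 1)
      if (all(mask[r0:(r0 + h), c0:(c0 + w)] == 0)) {
        mask[r0:(r0 + h), c0:(c0 + w)] <- i
        base <- sample(300:800, 1)
        img[r0:(r0 + h), c0:(c0 + w)] <-
          base + sample(0:30, (h + 1) * (w + 1), TRUE)
        for (b in seq_len(sample(0:2, 1))) {
          br <- sample(r0:(r0 + h), 1); bc <- sample(c0:(c0 + w), 1)
          rad <- sample(1:3, 1)
          for (r in max(r0, br - rad):min(r0 + h, br + rad))
            for (c in max(c0, bc - rad):min(c0 + w, bc + rad))
              if ((r - br)^2 + (c - bc)^2 <= rad^2)
                img[r, c] <- base * sample(c(2, 3, 4), 1) +
                  sample(0:5, 1)
        }
        break
      }
    }
  }
  list(image = img, mask = mask, background = bg)
}

# Exact upper-tail over-representation probability by exhaustive
# enumeration of all size-n subsets of a universe of size N.
enrichmentTailOracle <- function(N, K, n, k) {
  draws <- utils::combn(N, n)
  inCat <- colSums(draws <= K)  # categories taken as the first K members
  mean(inCat >= k)
}
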