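# Independent brute-force oracles used to freeze expected values.
# These deliberately re-derive each quantity with naive loops or complete
# enumeration, never through the package's own code paths.

# 3x3 in-bounds mean smoothing by nested loops.
oracle_smooth_3x3 <- function(x) {
  nr <- nrow(x); nc <- ncol(x)
  out <- matrix(0, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    ii <- max(1, i - 1):min(nr, i + 1)
    jj <- max(1, j - 1):min(nc, j + 1)
    out[i, j] <- mean(x[ii, jj])
  }
  out
}

# Flood-fill connected components (4- or 8-connectivity).
oracle_label <- function(mask, connectivity = 4) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  nb <- if (connectivity == 4) rbind(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  else rbind(c(-1, 0), c(1, 0), c(0, -1), c(0, 1),
             c(-1, -1), c(-1, 1), c(1, -1), c(1, 1))
  cur <- 0L
  for (sj in seq_len(nc)) for (si in seq_len(nr)) {
    if (!mask[si, sj] || lab[si, sj] > 0L) next
    cur <- cur + 1L
    queue <- list(c(si, sj)); lab[si, sj] <- cur
    while (length(queue)) {
      p <- queue[[1L]]; queue <- queue[-1L]
      for (d in seq_len(nrow(nb))) {
        r <- p[1] + nb[d, 1]; c <- p[2] + nb[d, 2]
        if (r >= 1 && r <= nr && c >= 1 && c <= nc &&
            mask[r, c] && lab[r, c] == 0L) {
          lab[r, c] <- cur
          queue[[length(queue) + 1L]] <- c(r, c)
        }
      }
    }
  }
  lab
}

# Exhaustive city-block dilation: TRUE wherever some seed pixel lies at
# Manhattan distance <= radius.
oracle_dilate_cityblock <- function(mask, radius) {
  nr <- nrow(mask); nc <- ncol(mask)
  seeds <- which(mask, arr.ind = TRUE)
  out <- matrix(FALSE, nr, nc)
  if (!nrow(seeds)) return(out)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    if (any(abs(seeds[, 1] - i) + abs(seeds[, 2] - j) <= radius))
      out[i, j] <- TRUE
  }
  out
}

# Perimeter of a logical region: region pixels 4-adjacent to the outside
# or lying on the image border.
oracle_perimeter <- function(region) {
  nr <- nrow(region); nc <- ncol(region)
  out <- matrix(FALSE, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    if (!region[i, j]) next
    if (i == 1 || i == nr || j == 1 || j == nc) { out[i, j] <- TRUE; next }
    if (!region[i - 1, j] || !region[i + 1, j] ||
        !region[i, j - 1] || !region[i, j + 1]) out[i, j] <- TRUE
  }
  out
}

# Complete-enumeration hypergeometric upper tail: over all C(N, n) draws
# from 1..N with category 1..K, the fraction with >= k category members.
oracle_hyper_tail <- function(N, K, n, k) {
  draws <- utils::combn(N, n)
  if (!is.matrix(draws)) draws <- matrix(draws, nrow = n)
  overlaps <- colSums(draws <= K)
  mean(overlaps >= k)
}

# Ray-casting point-in-polygon (even-odd rule), independent of pracma.
oracle_point_in_polygon <- function(px, py, xs, ys) {
  n <- length(xs)
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    if ((ys[i] > py) != (ys[j] > py)) {
      xint <- xs[i] + (py - ys[i]) / (ys[j] - ys[i]) * (xs[j] - xs[i])
      if (px < xint) inside <- !inside
    }
    j <- i
  }
  inside
}

# A deterministic skeleton fixture: centred plus sign on an odd square.
plus_skeleton <- function(n = 9L) {
  sk <- matrix(FALSE, n, n)
  mid <- (n + 1L) %/% 2L
  sk[mid, ] <- TRUE
  sk[, mid] <- TRUE
  sk
}
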