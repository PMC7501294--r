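# Programmatic fixtures: digital shapes and a square-grid membrane image.

digital_disc <- function(radius, pad = 3) {
  n <- 2 * (radius + pad) + 1
  c0 <- radius + pad + 1
  outer(1:n, 1:n, function(r, c) (r - c0)^2 + (c - c0)^2 <= radius^2)
}

digital_rect <- function(h, w, pad = 3) {
  m <- matrix(FALSE, h + 2 * pad, w + 2 * pad)
  m[pad + (1:h), pad + (1:w)] <- TRUE
  m
}

# plus sign built from five a x a squares
digital_cross <- function(a, pad = 3) {
  n <- 3 * a + 2 * pad
  m <- matrix(FALSE, n, n)
  m[pad + a + (1:a), pad + (1:(3 * a))] <- TRUE
  m[pad + (1:(3 * a)), pad + a + (1:a)] <- TRUE
  m
}

# square cells separated by bright lines of width `lw`, `k` cells per side
grid_membrane <- function(k = 3, cell = 30, lw = 2, bright = 1000) {
  n <- k * cell + (k + 1) * lw
  img <- matrix(0, n, n)
  for (i in 0:k) {
    pos <- i * (cell + lw) + (1:lw)
    img[pos, ] <- bright
    img[, pos] <- bright
  }
  img
}

# independent finite-difference gradient magnitude (oracle for gradient_map)
fd_gradient <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  gx <- matrix(0, nr, nc); gy <- matrix(0, nr, nc)
  for (r in 1:nr) for (cc in 1:nc) {
    gx[r, cc] <- (m[r, min(cc + 1, nc)] - m[r, max(cc - 1, 1)]) /
      (min(cc + 1, nc) - max(cc - 1, 1))
    gy[r, cc] <- (m[min(r + 1, nr), cc] - m[max(r - 1, 1), cc]) /
      (min(r + 1, nr) - max(r - 1, 1))
  }
  sqrt(gx^2 + gy^2)
}

small_mosaic <- function(seed = 1, n = 25, field = 400, ...) {
  generate_mosaic(mosaic_spec(field_size = field, n_fibres = n,
                              rng_seed = seed, ...))
}

# one-to-one matching of segmented regions to ground truth
match_truth <- function(feats, truth, max_dist = 3, max_area_err = 0.1) {
  used <- rep(FALSE, nrow(feats))
  ok <- logical(nrow(truth))
  for (i in seq_len(nrow(truth))) {
    d <- sqrt((feats$x - truth$x[i])^2 + (feats$y - truth$y[i])^2)
    d[used] <- Inf
    j <- which.min(d)
    if (length(j) == 1 && d[j] <= max_dist) {
      used[j] <- TRUE
      ok[i] <- abs(feats$area[j] - truth$area[i]) / truth$area[i] <= max_area_err
    }
  }
  ok
}
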