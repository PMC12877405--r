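# Shared helpers for building tiny deterministic fixtures in code.

# Paint a compact blob of exactly `k` pixels (the k pixels nearest the
# centre) with the given value.
paint_blob <- function(img, cx, cy, k, value = 1) {
  nr <- nrow(img); nc <- ncol(img)
  X <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  Y <- matrix(seq_len(nr), nr, nc)
  d <- (X - cx)^2 + (Y - cy)^2
  idx <- order(d)[seq_len(k)]
  img[idx] <- value
  img
}

# Horizontal sinusoidal stripes (fibers along x).
stripes_x <- function(nr = 64, nc = 64, period = 8) {
  Y <- matrix(seq_len(nr), nr, nc)
  0.5 + 0.5 * sin(2 * pi * Y / period)
}

# Axial circular mean of orientations in degrees [0, 180).
axial_mean <- function(theta_deg) {
  a <- 2 * theta_deg * pi / 180
  (atan2(mean(sin(a)), mean(cos(a))) / 2 * 180 / pi) %% 180
}

# Smallest axial angular difference between two orientations in degrees.
axial_diff <- function(a, b) {
  d <- abs(a - b) %% 180
  pmin(d, 180 - d)
}

# Match measured rows to truth rows by nearest centroid; returns truth idx.
nearest_truth <- function(mx, my, tx, ty) {
  vapply(seq_along(mx), function(i)
    which.min((tx - mx[i])^2 + (ty - my[i])^2), integer(1))
}
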