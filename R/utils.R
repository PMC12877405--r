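# Internal helpers shared by the imaging modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Mirror-pad a matrix by p pixels on every side (boundary row/col not repeated
# when the image is large enough; falls back to edge replication otherwise).
reflect_pad <- function(m, p) {
  nr <- nrow(m); nc <- ncol(m)
  ridx <- c(pmin(pmax(seq.int(p + 1, 2), 1), nr), seq_len(nr),
            pmin(pmax(seq.int(nr - 1, nr - p), 1), nr))
  cidx <- c(pmin(pmax(seq.int(p + 1, 2), 1), nc), seq_len(nc),
            pmin(pmax(seq.int(nc - 1, nc - p), 1), nc))
  if (p == 0) return(m)
  m[ridx, cidx, drop = FALSE]
}

# Local mean and standard deviation over a centred win x win square window,
# mirror-padded at the borders. Returns list(mean, sd).
box_mean_sd <- function(img, win) {
  stopifnot(win %% 2 == 1, win >= 1)
  p <- (win - 1L) / 2L
  pad <- reflect_pad(img, p)
  s1 <- box_sum(pad, win)
  s2 <- box_sum(pad * pad, win)
  n <- win * win
  mu <- s1 / n
  v <- pmax(s2 / n - mu * mu, 0)
  list(mean = mu, sd = sqrt(v))
}

# Sliding win x win sum of a padded matrix, valid region only.
box_sum <- function(pad, win) {
  cs <- apply(pad, 2, cumsum)
  cs <- rbind(0, cs)
  rows <- cs[seq.int(win + 1, nrow(cs)), , drop = FALSE] -
    cs[seq.int(1, nrow(cs) - win), , drop = FALSE]
  cs2 <- t(apply(rows, 1, cumsum))
  if (nrow(rows) == 1) cs2 <- matrix(cumsum(rows[1, ]), nrow = 1)
  cs2 <- cbind(0, cs2)
  cs2[, seq.int(win + 1, ncol(cs2)), drop = FALSE] -
    cs2[, seq.int(1, ncol(cs2) - win), drop = FALSE]
}

# Rescale to [0, 1]; constant images map to 0.
norm01 <- function(img) {
  r <- range(img)
  if (r[2] <= r[1]) return(img * 0)
  (img - r[1]) / (r[2] - r[1])
}

# Disk structuring element of the given pixel radius.
disc_brush <- function(radius) {
  EBImage::makeBrush(2L * as.integer(radius) + 1L, shape = "disc")
}

# Contrast-limited adaptive histogram equalisation with a relative clip
# limit (fraction of the tile's pixel count, e.g. 0.02 for a 2% clip) and a
# tile grid of ntiles x ntiles. Pads with mirrored borders so the image
# size is a tile multiple, then crops back. Output is scaled to [0, 1].
clahe_clip <- function(img, clip = 0.02, ntiles = 8L, bins = 256L) {
  x <- norm01(img)
  nr <- nrow(x); nc <- ncol(x)
  pr <- (ntiles - nr %% ntiles) %% ntiles
  pc <- (ntiles - nc %% ntiles) %% ntiles
  if (pr > 0) x <- x[c(seq_len(nr), rev(seq_len(nr))[seq_len(pr)]), , drop = FALSE]
  if (pc > 0) x <- x[, c(seq_len(nc), rev(seq_len(nc))[seq_len(pc)]), drop = FALSE]
  out <- EBImage::clahe(x, nx = ntiles, ny = ntiles, bins = bins,
                        limit = max(clip * bins, 1))
  out <- as.matrix(out)[seq_len(nr), seq_len(nc), drop = FALSE]
  norm01(out)
}

# Sobel gradients (d/dx along columns, d/dy along rows, y pointing down).
sobel_gradients <- function(img) {
  p <- reflect_pad(img, 1L)
  nr <- nrow(img); nc <- ncol(img)
  sh <- function(dr, dc) p[seq_len(nr) + 1L + dr, seq_len(nc) + 1L + dc, drop = FALSE]
  gx <- (sh(-1, 1) + 2 * sh(0, 1) + sh(1, 1)) -
        (sh(-1, -1) + 2 * sh(0, -1) + sh(1, -1))
  gy <- (sh(1, -1) + 2 * sh(1, 0) + sh(1, 1)) -
        (sh(-1, -1) + 2 * sh(-1, 0) + sh(-1, 1))
  list(gx = gx, gy = gy)
}

# Gaussian smoothing that tolerates sigma = 0 and plain matrices.
gauss_smooth <- function(img, sigma) {
  if (sigma <= 0) return(img)
  as.matrix(EBImage::gblur(img, sigma = sigma))
}

# Sauvola local threshold mask for bright features: the classic rule
# t = m * (1 + k * (s / R - 1)) over a (2 * radius + 1)^2 window assumes
# dark features on a bright page, so it is applied to the inverted image
# (bright fluorescence = "ink"); R is half the image dynamic range. In
# locally flat regions the threshold then sits above the local mean and
# background stays background.
sauvola_mask <- function(img, radius = 15L, k = 0.2) {
  win <- 2L * as.integer(radius) + 1L
  R <- diff(range(img)) / 2
  if (R <= 0) return(matrix(FALSE, nrow(img), ncol(img)))
  inv <- max(img) - img
  ms <- box_mean_sd(inv, win)
  thr <- ms$mean * (1 + k * (ms$sd / R - 1))
  inv < thr
}

`%||%` <- function(a, b) if (is.null(a)) b else a
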