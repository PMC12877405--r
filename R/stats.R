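#' Two-sample Kolmogorov-Smirnov comparison of angular samples
#'
#' The condition-level test for cumulative angular distributions (fiber or
#' FA orientations): `D = sup |ECDF_a - ECDF_b|`, with the exact p-value
#' when `n1 * n2 <= 10^4` (and no ties) and the asymptotic distribution
#' otherwise, as implemented by [stats::ks.test()].
#'
#' @param a,b non-empty numeric samples (e.g. folded angles).
#' @return a `ComparisonResult` list: `statistic`, `p_value`, `n1`, `n2`,
#'   `method = "ks"`.
#' @export
ks_two_sample <- function(a, b) {
  if (length(a) == 0 || length(b) == 0) stop("both samples must be non-empty")
  res <- suppressWarnings(ks.test(a, b,
                                  exact = length(a) * length(b) <= 1e4))
  comparison_result(unname(res$statistic), res$p.value,
                    length(a), length(b), "ks")
}

#' Mann-Whitney (Wilcoxon rank-sum) comparison
#'
#' The test used for per-cell count readouts (e.g. LC3B spots per cell):
#' U statistic with the exact null distribution for small samples without
#' ties and the tie-corrected normal approximation otherwise, via
#' [stats::wilcox.test()].
#'
#' @param a,b non-empty numeric samples.
#' @return a `ComparisonResult` list with `method = "mwu"` (`statistic` is
#'   the U count of `a` over `b`).
#' @export
mann_whitney <- function(a, b) {
  if (length(a) == 0 || length(b) == 0) stop("both samples must be non-empty")
  res <- suppressWarnings(wilcox.test(a, b))
  p <- res$p.value
  # fully tied samples: the normal approximation degenerates to 0/0, but
  # identical samples carry no evidence of a difference
  if (is.na(p)) p <- 1
  comparison_result(unname(res$statistic), p, length(a), length(b), "mwu")
}

comparison_result <- function(statistic, p_value, n1, n2, method) {
  stopifnot(p_value >= 0, p_value <= 1 + 1e-12)
  structure(list(statistic = statistic, p_value = min(p_value, 1),
                 n1 = n1, n2 = n2, method = method),
            class = "ComparisonResult")
}

#' @export
print.ComparisonResult <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, p = %.4g (n1 = %d, n2 = %d)\n",
              toupper(x$method), x$statistic, x$p_value, x$n1, x$n2))
  invisible(x)
}

#' Percentile-bootstrap 95% confidence band
#'
#' Resamples the independent units (images or cells, whichever the study
#' design treats as independent) with replacement. For scalar inputs the
#' band is a CI on the mean; for a list of `AngularDistribution`s it is a
#' pointwise band of the cumulative frequency over a 0-90 degree grid.
#'
#' @param per_unit_values numeric vector, or a list of
#'   [cumulative_distribution()] objects (one per unit).
#' @param n_boot bootstrap replicates (default 10000).
#' @param seed RNG seed for reproducibility.
#' @param level confidence level (default 0.95).
#' @return a `CIBand` list: `lower`, `upper` (scalars, or curves over
#'   `grid`), `level`, `n_boot`, `seed`.
#' @export
bootstrap_ci95 <- function(per_unit_values, n_boot = 10000, seed = 1,
                           level = 0.95) {
  alpha <- (1 - level) / 2
  with_seed(seed, {
    if (is.list(per_unit_values)) {
      stopifnot(all(vapply(per_unit_values, inherits, logical(1),
                           "AngularDistribution")))
      grid <- seq(0, 90, by = 1)
      n <- length(per_unit_values)
      curves <- vapply(per_unit_values,
                       function(d) d$cumulative(grid), numeric(length(grid)))
      boot <- matrix(0, length(grid), n_boot)
      for (bi in seq_len(n_boot)) {
        pick <- sample.int(n, n, replace = TRUE)
        boot[, bi] <- rowMeans(curves[, pick, drop = FALSE])
      }
      lower <- apply(boot, 1, quantile, probs = alpha)
      upper <- apply(boot, 1, quantile, probs = 1 - alpha)
      out <- list(lower = lower, upper = upper, grid = grid)
    } else {
      v <- as.numeric(per_unit_values)
      stopifnot(length(v) >= 1)
      boot <- vapply(seq_len(n_boot),
                     function(i) mean(sample(v, replace = TRUE)), numeric(1))
      out <- list(lower = unname(quantile(boot, alpha)),
                  upper = unname(quantile(boot, 1 - alpha)), grid = NULL)
    }
    stopifnot(all(out$lower <= out$upper + 1e-12))
    structure(c(out, list(level = level, n_boot = n_boot, seed = seed)),
              class = "CIBand")
  })
}

#' Scale values to an unstretched control
#'
#' Divides each value by the mean of the control condition, so the control
#' averages to 1 and all other conditions are expressed relative to it.
#'
#' @param values numeric vector to normalize.
#' @param control_values non-empty control sample with non-zero mean.
#' @return `values / mean(control_values)`.
#' @export
normalize_to_control <- function(values, control_values) {
  if (length(control_values) == 0) stop("empty control sample")
  m <- mean(control_values)
  if (!is.finite(m) || m == 0) stop("control mean is zero or non-finite")
  values / m
}
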