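# Sucrose-gradient fractionation profiles: per-condition normalization
# I_i / I_max, Akima interpolation between fraction data points, and a
# centroid statistic for distribution shifts between conditions.
#
# The centroid (intensity-weighted mean fraction index) is this package's
# scalar operationalization of "migrates with lower-density fractions";
# compact, sonication-resistant chromatin sediments to high-density
# fractions (large indices), so a negative centroid shift of condition A
# relative to condition B means A migrates with lower-density fractions.

#' Construct a gradient profile
#'
#' @param fraction strictly increasing integer fraction indices.
#' @param intensity non-negative signal intensities (arbitrary units).
#' @param normalized logical: are intensities already scaled to max = 1?
#' @return A `GradientProfile` data.frame.
#' @export
gradient_profile <- function(fraction, intensity, normalized = FALSE) {
  fraction <- as.integer(fraction)
  if (length(fraction) != length(intensity) || length(fraction) == 0)
    stop("fraction and intensity must be non-empty and equal length",
         call. = FALSE)
  if (any(diff(fraction) <= 0))
    stop("fraction indices must be strictly increasing", call. = FALSE)
  if (any(!is.finite(intensity)) || any(intensity < 0))
    stop("intensities must be finite and >= 0", call. = FALSE)
  out <- data.frame(fraction = fraction, intensity = as.numeric(intensity))
  class(out) <- c("GradientProfile", "data.frame")
  attr(out, "normalized") <- isTRUE(normalized)
  out
}

#' Read a gradient profile from CSV
#'
#' Expected columns: `fraction`, `intensity`, optionally `condition` and
#' `replicate`. With the optional columns present, one profile per
#' (condition, replicate) is returned.
#'
#' @param path CSV file path.
#' @return A single `GradientProfile`, or a nested list
#'   `profiles[[condition]][[replicate]]` when the optional columns exist.
#' @export
read_gradient_profile <- function(path) {
  if (!file.exists(path)) stop("profile not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("fraction", "intensity") %in% names(df)))
    stop("CSV must have columns fraction, intensity", call. = FALSE)
  if (!"condition" %in% names(df))
    return(gradient_profile(df$fraction, df$intensity))
  if (!"replicate" %in% names(df)) df$replicate <- 1L
  out <- list()
  for (cond in unique(df$condition)) {
    sub <- df[df$condition == cond, ]
    out[[cond]] <- lapply(split(sub, sub$replicate), function(r)
      gradient_profile(r$fraction[order(r$fraction)],
                       r$intensity[order(r$fraction)]))
  }
  out
}

#' Normalize a profile to its maximum
#'
#' Each intensity is divided by the profile maximum (I_i / I_max), so the
#' maximum maps to exactly 1. Idempotent and scale-invariant.
#'
#' @param raw a `GradientProfile` with at least one positive intensity.
#' @return The normalized `GradientProfile`.
#' @export
normalize_profile <- function(raw) {
  stopifnot(inherits(raw, "GradientProfile"))
  m <- max(raw$intensity)
  if (m <= 0)
    stop("normalization error: profile has no positive intensity",
         call. = FALSE)
  out <- gradient_profile(raw$fraction, raw$intensity / m,
                          normalized = TRUE)
  out
}

# Akima (1970) local cubic interpolation: knot slopes are the
# |slope-difference|-weighted averages of the neighboring secant slopes,
# with two quadratically extrapolated ghost slopes per end; evaluation is
# piecewise cubic Hermite. Local, overshoot-damping, exact at the knots,
# and reduces to the polyline on collinear data.
.akima_eval <- function(x, y, xi) {
  n <- length(x)
  m <- diff(y) / diff(x)
  M <- c(3 * m[1] - 2 * m[2],  2 * m[1] - m[2], m,
         2 * m[n - 1] - m[n - 2], 3 * m[n - 1] - 2 * m[n - 2])
  # slope at knot i uses interval slopes m_{i-2}..m_{i+1} = M[i..i+3]
  t <- numeric(n)
  for (i in seq_len(n)) {
    w1 <- abs(M[i + 3] - M[i + 2])
    w2 <- abs(M[i + 1] - M[i])
    t[i] <- if (w1 + w2 > 1e-12 * (abs(M[i + 2]) + abs(M[i + 1]) + 1)) {
      (w1 * M[i + 1] + w2 * M[i + 2]) / (w1 + w2)
    } else (M[i + 1] + M[i + 2]) / 2
  }
  bin <- pmin(pmax(findInterval(xi, x), 1L), n - 1L)
  h <- x[bin + 1L] - x[bin]
  s <- (xi - x[bin]) / h
  h00 <- (1 + 2 * s) * (1 - s)^2
  h10 <- s * (1 - s)^2
  h01 <- s^2 * (3 - 2 * s)
  h11 <- s^2 * (s - 1)
  h00 * y[bin] + h10 * h * t[bin] + h01 * y[bin + 1L] +
    h11 * h * t[bin + 1L]
}

#' Akima interpolation of a profile
#'
#' Evaluates an Akima spline through the fraction data points on a uniform
#' grid with `resolution` points per fraction. The curve passes through
#' every data point exactly and reproduces polylines on collinear data.
#'
#' @param profile a `GradientProfile` with >= 5 points (Akima minimum).
#' @param resolution grid points per unit fraction (default 10).
#' @return Data.frame with columns `fraction` (dense grid) and `intensity`.
#' @export
interpolate_profile <- function(profile, resolution = 10) {
  stopifnot(inherits(profile, "GradientProfile"))
  if (nrow(profile) < 5)
    stop("interpolation error: Akima interpolation needs >= 5 points",
         call. = FALSE)
  x <- as.numeric(profile$fraction)
  lo <- min(x); hi <- max(x)
  grid <- lo + seq.int(0L, round((hi - lo) * resolution)) / resolution
  yi <- .akima_eval(x, profile$intensity, grid)
  data.frame(fraction = grid, intensity = as.numeric(yi))
}

#' Centroid fraction of a profile
#'
#' Intensity-weighted mean fraction index: sum(i * w_i) / sum(w_i). Bounded
#' by the first and last fraction; translation-equivariant on the fraction
#' axis.
#'
#' @param profile a `GradientProfile`.
#' @return Numeric centroid fraction.
#' @export
profile_centroid <- function(profile) {
  stopifnot(inherits(profile, "GradientProfile"))
  w <- profile$intensity
  if (sum(w) <= 0) stop("profile has zero total intensity", call. = FALSE)
  sum(profile$fraction * w) / sum(w)
}

#' Centroid shift between two profiles
#'
#' Both profiles must be normalized and on the same fraction grid. The
#' shift is centroid(a) - centroid(b); a negative value means `a` migrates
#' with lower-density (smaller-index) fractions than `b`.
#'
#' @param a,b normalized `GradientProfile`s on a common grid.
#' @return List with `centroid_a`, `centroid_b` and `shift`.
#' @export
compare_profiles <- function(a, b) {
  stopifnot(inherits(a, "GradientProfile"), inherits(b, "GradientProfile"))
  if (!isTRUE(attr(a, "normalized")) || !isTRUE(attr(b, "normalized")))
    stop("profiles must be normalized before comparison", call. = FALSE)
  if (!identical(a$fraction, b$fraction))
    stop("grid error: profiles are on different fraction grids",
         call. = FALSE)
  ca <- profile_centroid(a); cb <- profile_centroid(b)
  list(centroid_a = ca, centroid_b = cb, shift = ca - cb)
}

#' Combine replicate profiles
#'
#' Replicates are normalized individually, then averaged fraction-wise
#' (mean of replicates after normalization).
#'
#' @param profiles list of `GradientProfile`s on a common grid.
#' @return A normalized mean `GradientProfile`.
#' @export
combine_replicates <- function(profiles) {
  stopifnot(length(profiles) >= 1)
  normed <- lapply(profiles, normalize_profile)
  frac <- normed[[1]]$fraction
  for (p in normed[-1])
    if (!identical(p$fraction, frac))
      stop("grid error: replicates are on different fraction grids",
           call. = FALSE)
  m <- rowMeans(do.call(cbind, lapply(normed, function(p) p$intensity)))
  gradient_profile(frac, m / max(m), normalized = TRUE)
}

#' Synthetic fractionation profiles
#'
#' Gaussian-peaked profiles over 20 fractions emulating the two migration
#' regimes of centromeric chromatin: `"wt_like"` peaks in the high-density
#' fractions (12-20, compact chromatin), `"depleted_like"` peaks in the
#' low-density fractions (5-15, chromatin rendered sonication-accessible
#' by loss of its compaction factor). Multiplicative log-normal noise
#' emulates blot densitometry variation between replicates.
#'
#' @param condition `"wt_like"` or `"depleted_like"`.
#' @param n_fractions number of fractions (default 20).
#' @param noise_sd log-normal noise s.d. (0 = noiseless).
#' @param seed RNG seed (required when `noise_sd > 0`).
#' @return A raw (unnormalized) `GradientProfile`.
#' @export
synth_gradient_profile <- function(condition = c("wt_like",
                                                 "depleted_like"),
                                   n_fractions = 20, noise_sd = 0.1,
                                   seed = NULL) {
  condition <- match.arg(condition)
  center <- if (condition == "wt_like") 16 else 10
  width <- 2.5
  i <- seq_len(n_fractions)
  base <- 100 * exp(-(i - center)^2 / (2 * width^2)) + 2
  y <- if (noise_sd > 0) {
    if (is.null(seed))
      stop("seed required for noisy synthetic profiles", call. = FALSE)
    .with_seed(seed, base * exp(stats::rnorm(n_fractions, 0, noise_sd)))
  } else base
  gradient_profile(i, y)
}
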