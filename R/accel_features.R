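#' Names of the 21 geometric accelerometer channels
#'
#' The tri-axial signal is expanded into every geometric transformation of
#' angles and distances in one, two and three dimensions: the raw axes, the
#' four resultant-vector magnitudes, six planar/axis angles, three solid
#' angles of the resultant pyramid, the cuboid volume, and four areas.
#'
#' @return Character vector of length 21.
#' @export
accel_channels <- function() {
  c(
    "x", "y", "z",
    "r_xyz", "r_xy", "r_xz", "r_yz",
    "theta_xy", "theta_xz", "theta_yz", "theta_z", "theta_y", "theta_x",
    "omega_x", "omega_y", "omega_z",
    "v_xyz",
    "a_x", "a_y", "a_z", "a_xyz"
  )
}

#' Names of the 10 per-channel window statistics
#'
#' Five location/spread summaries, two quartiles, and three discrete-Fourier
#' descriptors (dominant amplitude, dominant period in seconds, spectral
#' energy).
#'
#' @return Character vector of length 10.
#' @export
window_stat_names <- function() {
  c("mean", "sd", "median", "min", "max", "q1", "q3",
    "dom_amp", "dom_period_s", "spec_energy")
}

# atan2 that is undefined (NA) when both arguments vanish.
.atan2_na <- function(y, x) {
  out <- atan2(y, x)
  out[x == 0 & y == 0] <- NA_real_
  out
}

# asin with arguments clamped to [-1, 1]; clamping can only arise from
# floating-point rounding (the arguments are Cauchy-Schwarz bounded).
# The number of clamped values is recorded in attr(, "n_clamped").
.asin_clamped <- function(v) {
  n_cl <- sum(abs(v) > 1, na.rm = TRUE)
  out <- asin(pmin(1, pmax(-1, v)))
  attr(out, "n_clamped") <- n_cl
  out
}

#' Expand tri-axial samples into the 21 geometric channels
#'
#' @param ax,ay,az numeric vectors of accelerations (m/s^2).
#' @return A numeric matrix with one row per sample and the 21 columns of
#'   [accel_channels()]. Angles use the two-argument arctangent; degenerate
#'   denominators (zero resultant in the relevant plane) yield `NA`. Signed
#'   products (volume, planar areas) are kept signed. The attribute
#'   `n_clamped` counts arcsine arguments clamped to \[-1, 1\].
#' @export
geometric_transform <- function(ax, ay, az) {
  stopifnot(length(ax) == length(ay), length(ay) == length(az))
  r_xy <- sqrt(ax^2 + ay^2)
  r_xz <- sqrt(ax^2 + az^2)
  r_yz <- sqrt(ay^2 + az^2)
  r_xyz <- sqrt(ax^2 + ay^2 + az^2)

  om_x <- ay * az / (r_xy * r_xz)
  om_y <- ax * az / (r_xy * r_yz)
  om_z <- ax * ay / (r_xz * r_yz)
  om_x[r_xy * r_xz == 0] <- NA_real_
  om_y[r_xy * r_yz == 0] <- NA_real_
  om_z[r_xz * r_yz == 0] <- NA_real_
  n_cl <- 0L
  om <- lapply(list(om_x, om_y, om_z), .asin_clamped)
  n_cl <- sum(vapply(om, function(v) attr(v, "n_clamped"), integer(1)))

  out <- cbind(
    x = ax, y = ay, z = az,
    r_xyz = r_xyz, r_xy = r_xy, r_xz = r_xz, r_yz = r_yz,
    theta_xy = .atan2_na(ay, ax),
    theta_xz = .atan2_na(az, ax),
    theta_yz = .atan2_na(az, ay),
    theta_z = .atan2_na(az, r_xy),
    theta_y = .atan2_na(ay, r_xz),
    theta_x = .atan2_na(ax, r_yz),
    omega_x = as.numeric(om[[1]]),
    omega_y = as.numeric(om[[2]]),
    omega_z = as.numeric(om[[3]]),
    v_xyz = ax * ay * az,
    a_x = ay * az, a_y = ax * az, a_z = ax * ay,
    a_xyz = 0.5 * sqrt((ay * az)^2 + (ax * az)^2 + (ax * ay)^2)
  )
  attr(out, "n_clamped") <- n_cl
  out
}

#' Ten summary statistics of one channel over one window
#'
#' Summary statistics are computed over the finite samples. The Fourier
#' statistics use the unnormalized discrete Fourier transform of the raw
#' (mean-retained, finite) series: the dominant amplitude is the maximum
#' modulus over the positive-frequency bins `1..floor(n/2)` (the DC bin is
#' excluded unless `include_dc = TRUE`), the dominant period is the window
#' duration divided by the winning bin index, and the spectral energy is the
#' sum of squared moduli over all bins (DC included).
#'
#' @param x numeric series sampled over the window.
#' @param duration_s window duration in seconds.
#' @param include_dc logical; include the DC bin in the dominant-amplitude
#'   search (default `FALSE`).
#' @return Named numeric vector of length 10 ([window_stat_names()]); all
#'   `NA` when fewer than 2 finite samples remain.
#' @export
window_statistics <- function(x, duration_s = 3, include_dc = FALSE) {
  x <- x[is.finite(x)]
  n <- length(x)
  out <- stats::setNames(rep(NA_real_, 10L), window_stat_names())
  if (n < 2L) return(out)
  q <- stats::quantile(x, c(0, 0.25, 0.5, 0.75, 1), names = FALSE, type = 7)
  mod <- Mod(stats::fft(x))
  nh <- n %/% 2L
  if (include_dc) {
    k <- which.max(mod[seq_len(nh + 1L)]) - 1L
    amp <- mod[k + 1L]
  } else {
    k <- which.max(mod[1L + seq_len(nh)])
    amp <- mod[1L + k]
  }
  out["mean"] <- mean(x)
  out["sd"] <- stats::sd(x)
  out["min"] <- q[1]; out["q1"] <- q[2]; out["median"] <- q[3]
  out["q3"] <- q[4]; out["max"] <- q[5]
  out["dom_amp"] <- amp
  out["dom_period_s"] <- if (amp > 0 && k > 0) duration_s / k else NA_real_
  out["spec_energy"] <- sum(mod^2)
  out
}

# Vectorized window statistics over the columns of a complete (NA-free)
# matrix. Falls back to window_statistics() column-wise where NAs occur.
.window_stats_matrix <- function(X, duration_s, include_dc = FALSE) {
  n <- nrow(X); m <- ncol(X)
  res <- matrix(NA_real_, nrow = 10L, ncol = m,
                dimnames = list(window_stat_names(), colnames(X)))
  if (n < 2L || m == 0L) return(res)
  has_na <- colSums(!is.finite(X)) > 0L
  ok <- which(!has_na)
  if (length(ok)) {
    Xo <- X[, ok, drop = FALSE]
    mu <- colMeans(Xo)
    res["mean", ok] <- mu
    ss <- colSums(Xo^2) - n * mu^2
    res["sd", ok] <- sqrt(pmax(ss, 0) / (n - 1))
    # sort every column at once: radix order on (column, value)
    S <- matrix(Xo[order(col(Xo), Xo)], nrow = n)
    for (nm in c("min", "q1", "median", "q3", "max")) {
      p <- c(min = 0, q1 = 0.25, median = 0.5, q3 = 0.75, max = 1)[[nm]]
      h <- (n - 1) * p + 1
      lo <- floor(h); hi <- ceiling(h)
      res[nm, ok] <- S[lo, ] + (h - lo) * (S[hi, ] - S[lo, ])
    }
    Fm <- Mod(stats::mvfft(Xo))
    res["spec_energy", ok] <- colSums(Fm^2)
    nh <- n %/% 2L
    if (include_dc) {
      H <- Fm[seq_len(nh + 1L), , drop = FALSE]
      kstar <- max.col(t(H), ties.method = "first") - 1L
      amp <- H[cbind(kstar + 1L, seq_along(ok))]
    } else {
      H <- Fm[1L + seq_len(nh), , drop = FALSE]
      kstar <- max.col(t(H), ties.method = "first")
      amp <- H[cbind(kstar, seq_along(ok))]
    }
    res["dom_amp", ok] <- amp
    per <- ifelse(amp > 0 & kstar > 0, duration_s / kstar, NA_real_)
    res["dom_period_s", ok] <- per
  }
  for (j in which(has_na)) {
    res[, j] <- window_statistics(X[, j], duration_s, include_dc)
  }
  res
}

#' Accelerometer feature names (210)
#'
#' @return Character vector `"<channel>__<stat>"`, channel-major.
#' @export
accel_feature_names <- function() {
  as.vector(t(outer(accel_channels(), window_stat_names(), paste, sep = "__")))
}

#' Per-window accelerometer feature matrix
#'
#' Expands resampled 32 Hz samples of one animal segment into the 21 geometric
#' channels and summarizes each channel with the 10 window statistics,
#' yielding 210 named features per window.
#'
#' @param samples data frame with columns `t`, `ax`, `ay`, `az`, uniformly
#'   sampled (use [resample_accel()]).
#' @param windows data frame from [make_windows()].
#' @param rate sampling rate in Hz (default 32), used for the valid-sample
#'   quorum.
#' @param min_valid_frac minimum fraction of expected samples a window must
#'   contain; below it the row is emitted all-missing (default 0.5).
#' @param include_dc see [window_statistics()].
#' @return Numeric matrix, one row per window (rownames = window index), 210
#'   columns named `"<channel>__<stat>"`.
#' @export
accel_feature_matrix <- function(samples, windows, rate = 32,
                                 min_valid_frac = 0.5, include_dc = FALSE) {
  nw <- nrow(windows)
  fn <- accel_feature_names()
  out <- matrix(NA_real_, nrow = nw, ncol = length(fn),
                dimnames = list(windows$index, fn))
  if (nw == 0L || nrow(samples) == 0L) return(out)
  wi <- assign_windows(samples$t, windows)
  keep <- !is.na(wi)
  if (!any(keep)) return(out)
  dur <- windows$end[1] - windows$start[1]
  expected <- rate * dur
  cnt <- tabulate(wi[keep], nbins = nw)
  ch <- geometric_transform(samples$ax, samples$ay, samples$az)
  n_bad <- 0L
  # Fast path: all complete windows share one sample count, so their channel
  # series stack into a single (samples-per-window x windows*21) matrix and
  # the statistics vectorize across columns.
  nspw <- max(cnt)
  complete <- which(cnt == nspw & cnt >= min_valid_frac * expected)
  if (length(complete)) {
    ord <- order(wi)
    ord <- ord[!is.na(wi[ord])]
    ord <- ord[wi[ord] %in% complete]
    big <- ch[ord, , drop = FALSE]
    nc <- length(complete)
    # big is (nc * nspw) rows x 21 channels, grouped by window; refolding it
    # column-major gives nspw rows x (nc * 21) columns, channel-major blocks
    X <- matrix(big, nrow = nspw)
    st <- .window_stats_matrix(X, dur, include_dc)
    for (j in seq_len(21L)) {
      cols <- (j - 1L) * 10L + seq_len(10L)
      out[complete, cols] <- t(st[, (j - 1L) * nc + seq_len(nc), drop = FALSE])
    }
  }
  for (w in setdiff(which(cnt > 0L), complete)) {
    if (cnt[w] < min_valid_frac * expected) {
      n_bad <- n_bad + 1L
      next
    }
    rows <- which(wi == w)
    st <- .window_stats_matrix(ch[rows, , drop = FALSE], dur, include_dc)
    out[w, ] <- as.vector(st)  # stat-major within channel, matches names
  }
  if (n_bad > 0L) {
    message(sprintf("accel_feature_matrix: %d window(s) below the %d%% valid-sample quorum emitted as missing",
                    n_bad, round(100 * min_valid_frac)))
  }
  out
}
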