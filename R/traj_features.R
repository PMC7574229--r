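# Individual trajectory features from 1 Hz projected GPS positions:
# net/gross ratio, speed statistics, Brownian-motion scaling, turning-angle
# circular statistics, absolute tangential velocity, mean-squared-displacement
# power-law fit, and first-passage-time descriptors.

#' Step speeds of a trajectory
#'
#' @param x,y metric coordinates.
#' @param t timestamps in seconds (default unit spacing).
#' @return Speeds between consecutive fixes (m/s), length `n - 1`; empty for
#'   fewer than 2 positions.
#' @export
step_speeds <- function(x, y, t = seq_along(x)) {
  n <- length(x)
  if (n < 2L) return(numeric(0))
  sqrt(diff(x)^2 + diff(y)^2) / diff(as.numeric(t))
}

# Wrap angles to (-pi, pi].
.wrap_angle <- function(a) {
  w <- a %% (2 * pi)
  w[!is.na(w) & w > pi] <- w[!is.na(w) & w > pi] - 2 * pi
  w
}

#' Turning angles of a trajectory
#'
#' Wrapped differences of successive step headings; zero-length displacements
#' have undefined headings and produce `NA` angles.
#'
#' @param x,y metric coordinates (at least 3 positions).
#' @return Angles in `(-pi, pi]`, length `n - 2`.
#' @export
turning_angles <- function(x, y) {
  n <- length(x)
  if (n < 3L) return(numeric(0))
  dx <- diff(x); dy <- diff(y)
  h <- atan2(dy, dx)
  h[dx == 0 & dy == 0] <- NA_real_
  .wrap_angle(diff(h))
}

#' Mean resultant length of circular data
#'
#' @param angles numeric angles in radians; `NA`s are ignored.
#' @return Concentration in \[0, 1\] (`NA` when no finite angle remains).
#' @export
circular_rho <- function(angles) {
  a <- angles[is.finite(angles)]
  if (length(a) == 0L) return(NA_real_)
  sqrt(mean(cos(a))^2 + mean(sin(a))^2)
}

#' Lag-1 autocorrelation (biased estimator)
#'
#' `sum((x_t - xbar)(x_{t+1} - xbar)) / sum((x_t - xbar)^2)` over the finite
#' values (non-finite entries are dropped before forming lag pairs).
#'
#' @param x numeric series.
#' @return Correlation value; `NA` for fewer than 3 finite values or zero
#'   variance.
#' @export
acf_lag1 <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 3L) return(NA_real_)
  m <- mean(x)
  den <- sum((x - m)^2)
  if (den == 0) return(NA_real_)
  sum((x[-n] - m) * (x[-1] - m)) / den
}

#' Absolute tangential velocity along a trajectory
#'
#' The linear speed of motion along the local circular arc: at each interior
#' fix, |heading change per second| times the circumradius of the three
#' consecutive fixes. Collinear triples (infinite radius) and zero-length
#' displacements give `NA`; statistics downstream are computed over the
#' defined values only.
#'
#' @param x,y metric coordinates (at least 3 positions).
#' @param t timestamps in seconds.
#' @return Values per interior fix, length `n - 2`.
#' @export
tangential_velocity <- function(x, y, t = seq_along(x)) {
  n <- length(x)
  if (n < 3L) return(numeric(0))
  t <- as.numeric(t)
  i <- 2:(n - 1)
  ax <- x[i - 1]; ay <- y[i - 1]
  bx <- x[i];     by <- y[i]
  cx <- x[i + 1]; cy <- y[i + 1]
  v1x <- bx - ax; v1y <- by - ay
  v2x <- cx - bx; v2y <- cy - by
  h1 <- atan2(v1y, v1x); h1[v1x == 0 & v1y == 0] <- NA_real_
  h2 <- atan2(v2y, v2x); h2[v2x == 0 & v2y == 0] <- NA_real_
  dth <- .wrap_angle(h2 - h1)
  dt_mid <- (t[i + 1] - t[i - 1]) / 2
  a <- sqrt(v1x^2 + v1y^2)
  b <- sqrt(v2x^2 + v2y^2)
  cc <- sqrt((cx - ax)^2 + (cy - ay)^2)
  K <- 0.5 * abs((bx - ax) * (cy - ay) - (cx - ax) * (by - ay))
  R <- ifelse(K > 0, a * b * cc / (4 * K), NA_real_)
  abs(dth / dt_mid) * R
}

#' Net/gross displacement ratio
#'
#' Distance between first and last position divided by total path length.
#'
#' @param x,y metric coordinates.
#' @return Value in \[0, 1\]; `NA` when the path length is zero.
#' @export
net_gross_ratio <- function(x, y) {
  if (length(x) < 2L) return(NA_real_)
  gross <- sum(sqrt(diff(x)^2 + diff(y)^2))
  if (gross == 0) return(NA_real_)
  net <- sqrt((x[length(x)] - x[1])^2 + (y[length(y)] - y[1])^2)
  net / gross
}

#' Brownian-motion scaling parameter of a trajectory
#'
#' Square-root-time-normalized displacement increments per axis, centred by
#' the mean per-time increment, pooled over both axes:
#' `sqrt((mean(cx^2) + mean(cy^2)) / 2)` where
#' `cx = dx/sqrt(dt) - mean(dx/dt)` (and likewise for y). At the 1 s fix
#' interval used throughout, the two normalizations coincide.
#'
#' @param x,y metric coordinates.
#' @param t timestamps in seconds.
#' @return Scale in m/sqrt(s); `NA` with no displacements.
#' @export
brownian_scaling <- function(x, y, t = seq_along(x)) {
  if (length(x) < 2L) return(NA_real_)
  dt <- diff(as.numeric(t))
  dx <- diff(x); dy <- diff(y)
  cx <- dx / sqrt(dt) - mean(dx / dt)
  cy <- dy / sqrt(dt) - mean(dy / dt)
  sqrt((mean(cx^2) + mean(cy^2)) / 2)
}

#' Mean-squared-displacement power-law fit
#'
#' `MSD(tau)`, the mean over all overlapping fix pairs `tau` apart of the
#' squared displacement, is fitted as `MSD = a * tau^b` by least squares of
#' `log MSD` on `log tau`.
#'
#' @param x,y metric coordinates at 1 Hz.
#' @param taus integer lags in samples (default 1:6).
#' @return Named vector `c(msd_a, msd_b)`; both `NA` when any `MSD(tau)` is
#'   zero or a lag has no pair.
#' @export
msd_fit <- function(x, y, taus = 1:6) {
  n <- length(x)
  if (n < max(taus) + 2L) return(c(msd_a = NA_real_, msd_b = NA_real_))
  msd <- vapply(taus, function(tau) {
    i <- seq_len(n - tau)
    mean((x[i + tau] - x[i])^2 + (y[i + tau] - y[i])^2)
  }, numeric(1))
  if (any(msd == 0)) return(c(msd_a = NA_real_, msd_b = NA_real_))
  fit <- stats::lm.fit(cbind(1, log(taus)), log(msd))
  c(msd_a = exp(unname(fit$coefficients[1])), msd_b = unname(fit$coefficients[2]))
}

#' First-passage-time features of a trajectory
#'
#' First passage time at a fix and radius is the time for the path to first
#' exit the circle of that radius centred at the fix; the default convention
#' sums the backward and forward exit times. Fixes whose circle is never
#' exited within the segment are censored and excluded. Features: mean FPT
#' and variance of log FPT at 5 m; lag-1 autocorrelation of the 5 m FPT
#' series; the integer radius (1--10 m) maximizing the variance of log FPT;
#' and the slope of log mean FPT on log radius.
#'
#' @param x,y metric coordinates.
#' @param t timestamps in seconds.
#' @param radii increasing radii in metres (default 1:10).
#' @param mode `"both"` (backward + forward, default) or `"forward"`.
#' @param ref_radius radius used for the single-radius features (default 5).
#' @return Named vector `c(fpt_mean_5m, fpt_varlog_5m, fpt_acf1_5m,
#'   fpt_argmax_var_radius, fpt_loglog_slope)`.
#' @export
fpt_features <- function(x, y, t = seq_along(x), radii = 1:10,
                         mode = c("both", "forward"), ref_radius = 5) {
  mode <- match.arg(mode)
  out <- c(fpt_mean_5m = NA_real_, fpt_varlog_5m = NA_real_,
           fpt_acf1_5m = NA_real_, fpt_argmax_var_radius = NA_real_,
           fpt_loglog_slope = NA_real_)
  n <- length(x)
  if (n < 2L) return(out)
  t <- as.numeric(t)
  fwd <- fpt_exit_times(x, y, t, radii, 1L)
  if (mode == "both") {
    bwd <- fpt_exit_times(x, y, t, radii, -1L)
    FPT <- fwd + bwd  # NA propagates: censored in either direction
  } else {
    FPT <- fwd
  }
  vl <- apply(FPT, 2L, function(v) {
    v <- v[is.finite(v) & v > 0]
    if (length(v) < 2L) NA_real_ else stats::var(log(v))
  })
  mu <- colMeans(FPT, na.rm = TRUE)
  mu[!is.finite(mu)] <- NA_real_
  ir <- which(radii == ref_radius)
  if (length(ir) == 1L) {
    v5 <- FPT[, ir]
    if (any(is.finite(v5))) {
      out["fpt_mean_5m"] <- mean(v5, na.rm = TRUE)
      out["fpt_varlog_5m"] <- vl[ir]
      out["fpt_acf1_5m"] <- acf_lag1(v5)
    }
  }
  if (any(is.finite(vl))) out["fpt_argmax_var_radius"] <- radii[which.max(vl)]
  ok <- is.finite(mu) & mu > 0
  if (sum(ok) >= 2L) {
    fit <- stats::lm.fit(cbind(1, log(radii[ok])), log(mu[ok]))
    out["fpt_loglog_slope"] <- unname(fit$coefficients[2])
  }
  out
}

#' Names of the 27 individual GPS features
#'
#' @param subset `"all"` (27 features) or `"window"`: the 24-feature subset
#'   used at the 3 s window scale, which drops the MSD power-law coefficients
#'   and the Brownian scaling parameter (not estimable from <= 4 fixes).
#' @return Character vector.
#' @export
individual_feature_names <- function(subset = c("all", "window")) {
  subset <- match.arg(subset)
  nm <- c(
    "ngr",
    "spd_mean", "spd_sd", "spd_median", "spd_min", "spd_max", "spd_q1",
    "spd_q3", "spd_acf1", "spd_bms",
    "turn_rho", "turn_abs_acf1",
    "tv_mean", "tv_sd", "tv_median", "tv_min", "tv_max", "tv_q1", "tv_q3",
    "tv_acf1",
    "msd_a", "msd_b",
    "fpt_mean_5m", "fpt_varlog_5m", "fpt_acf1_5m", "fpt_argmax_var_radius",
    "fpt_loglog_slope"
  )
  if (subset == "window") nm <- setdiff(nm, c("msd_a", "msd_b", "spd_bms"))
  nm
}

# min/q1/median/q3/max/mean/sd over defined values; NA when empty.
.dist_stats <- function(v, prefix) {
  v <- v[is.finite(v)]
  if (length(v) == 0L) {
    q <- rep(NA_real_, 5); m <- NA_real_; s <- NA_real_
  } else {
    q <- stats::quantile(v, c(0, 0.25, 0.5, 0.75, 1), names = FALSE, type = 7)
    m <- mean(v)
    s <- if (length(v) > 1L) stats::sd(v) else NA_real_
  }
  stats::setNames(
    c(m, s, q[3], q[1], q[5], q[2], q[4]),
    paste0(prefix, c("_mean", "_sd", "_median", "_min", "_max", "_q1", "_q3"))
  )
}

#' Individual GPS feature vector for one trajectory window
#'
#' Computes all 27 trajectory features on an ordered 1 Hz position series.
#' Preconditions not met by short windows (e.g., MSD lags longer than the
#' window, fully censored first-passage circles) propagate as `NA`.
#'
#' @param x,y metric coordinates.
#' @param t timestamps in seconds.
#' @param radii FPT radii in metres (default 1:10).
#' @param taus MSD lags in seconds (default 1:6).
#' @param fpt_mode see [fpt_features()].
#' @return Named numeric vector of length 27 ([individual_feature_names()]).
#' @export
individual_gps_features <- function(x, y, t = seq_along(x), radii = 1:10,
                                    taus = 1:6, fpt_mode = "both") {
  sp <- step_speeds(x, y, t)
  ta <- turning_angles(x, y)
  tv <- tangential_velocity(x, y, t)
  out <- c(
    ngr = net_gross_ratio(x, y),
    .dist_stats(sp, "spd"),
    spd_acf1 = acf_lag1(sp),
    spd_bms = brownian_scaling(x, y, t),
    turn_rho = circular_rho(ta),
    turn_abs_acf1 = acf_lag1(abs(ta)),
    .dist_stats(abs(tv), "tv"),
    tv_acf1 = acf_lag1(abs(tv)),
    msd_fit(x, y, taus),
    fpt_features(x, y, t, radii, fpt_mode)
  )
  out[individual_feature_names()]
}
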