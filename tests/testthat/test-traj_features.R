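# Brute-force MSD and FPT oracles, reimplemented directly from their
# definitions for cross-checking.
oracle_msd <- function(x, y, taus) {
  vapply(taus, function(tau) {
    i <- seq_len(length(x) - tau)
    mean((x[i + tau] - x[i])^2 + (y[i + tau] - y[i])^2)
  }, numeric(1))
}

oracle_fpt_one <- function(x, y, t, i, r) {
  d <- sqrt((x - x[i])^2 + (y - y[i])^2)
  one_dir <- function(idx) {
    for (j in idx) {
      if (d[j] >= r) {
        prev <- if (j > i) j - 1 else j + 1
        if (d[j] == d[prev]) return(abs(t[j] - t[i]))
        tc <- t[prev] + (r - d[prev]) / (d[j] - d[prev]) * (t[j] - t[prev])
        return(abs(tc - t[i]))
      }
    }
    NA_real_
  }
  fwd <- if (i < length(x)) one_dir((i + 1):length(x)) else NA_real_
  bwd <- if (i > 1) one_dir((i - 1):1) else NA_real_
  fwd + bwd
}

test_that("step speeds behave on straight, stationary and random paths", {
  expect_equal(step_speeds(0:9, rep(0, 10)), rep(1, 9))
  expect_equal(step_speeds(rep(2, 5), rep(3, 5)), rep(0, 4))
  expect_length(step_speeds(1, 1), 0)
  # Rayleigh mean: iid N(0, sigma^2) steps per axis -> mean speed sigma*sqrt(pi/2)
  set.seed(20)
  sigma <- 0.7
  sp <- step_speeds(cumsum(rnorm(2e4, 0, sigma)), cumsum(rnorm(2e4, 0, sigma)))
  expect_equal(mean(sp), sigma * sqrt(pi / 2), tolerance = 0.02)
})

test_that("turning angles and circular concentration follow circular statistics", {
  expect_equal(turning_angles(0:9, rep(0, 10)), rep(0, 8))
  expect_equal(circular_rho(turning_angles(0:9, rep(0, 10))), 1)
  # alternating +90/-90 path
  x <- c(0, 1, 1, 2, 2, 3); y <- c(0, 0, 1, 1, 2, 2)
  expect_equal(abs(turning_angles(x, y)), rep(pi / 2, 4))
  # uniform random headings: rho -> 0
  set.seed(21)
  h <- runif(5e3, -pi, pi)
  x2 <- cumsum(cos(h)); y2 <- cumsum(sin(h))
  expect_lt(circular_rho(turning_angles(x2, y2)), 0.05)
  # direct evaluations
  expect_equal(circular_rho(rep(1.3, 7)), 1)
  expect_equal(circular_rho(c(0, pi / 2, pi, 3 * pi / 2)), 0, tolerance = 1e-12)
  expect_equal(circular_rho(c(0, pi / 2)), sqrt(2) / 2)
  expect_true(is.na(circular_rho(numeric(0))))
})

test_that("lag-1 autocorrelation uses the biased estimator", {
  expect_equal(acf_lag1(rep(c(1, -1), 50)), -99 / 100)
  expect_gt(acf_lag1(seq_len(5000)), 0.999)
  set.seed(22)
  expect_lt(abs(acf_lag1(rnorm(1e4))), 0.05)
  expect_true(is.na(acf_lag1(rep(1, 10))))
  # agrees with stats::acf's estimator
  x <- rnorm(500)
  expect_equal(acf_lag1(x),
               unname(stats::acf(x, lag.max = 1, plot = FALSE,
                                 demean = TRUE)$acf[2]),
               tolerance = 1e-12)
})

test_that("tangential velocity recovers circular motion and is undefined on lines", {
  th <- 0.1 * (0:60)
  x <- 10 * cos(th); y <- 10 * sin(th)
  tv <- tangential_velocity(x, y, 0:60)
  expect_equal(tv, rep(1, 59), tolerance = 1e-9)
  expect_true(all(is.na(tangential_velocity(0:9, rep(0, 10)))))  # collinear
  expect_true(all(is.na(tangential_velocity(rep(1, 5), rep(1, 5)))))  # stationary
})

test_that("net/gross ratio covers straight, closed and right-angle paths", {
  expect_equal(net_gross_ratio(0:5, rep(0, 6)), 1)
  expect_equal(net_gross_ratio(c(0, 1, 1, 0, 0), c(0, 0, 1, 1, 0)), 0)
  expect_equal(net_gross_ratio(c(0, 1, 1), c(0, 0, 1)), sqrt(2) / 2)
  expect_true(is.na(net_gross_ratio(rep(0, 4), rep(0, 4))))
})

test_that("Brownian scaling recovers the increment scale and is homogeneous", {
  expect_equal(brownian_scaling(0:99, 2 * (0:99)), 0)  # constant velocity
  set.seed(23)
  n <- 1e5
  x <- cumsum(rnorm(n + 1, 0, 2)); y <- cumsum(rnorm(n + 1, 0, 2))
  expect_equal(brownian_scaling(x, y), 2, tolerance = 0.02)
  w <- random_walk(200, seed = 24)
  expect_equal(brownian_scaling(2 * w$x, 2 * w$y), 2 * brownian_scaling(w$x, w$y))
})

test_that("MSD power-law fit separates ballistic from diffusive motion", {
  fit <- msd_fit(0:19, rep(0, 20))
  expect_equal(unname(fit["msd_a"]), 1, tolerance = 1e-9)
  expect_equal(unname(fit["msd_b"]), 2, tolerance = 1e-9)
  set.seed(25)
  w <- random_walk(1e4, step_sd = 1)
  expect_equal(unname(msd_fit(w$x, w$y)["msd_b"]), 1, tolerance = 0.1)
  expect_true(all(is.na(msd_fit(rep(0, 20), rep(0, 20)))))
  # matches brute-force MSD values exactly
  w2 <- random_walk(50, seed = 26)
  msd <- oracle_msd(w2$x, w2$y, 1:6)
  co <- stats::coef(stats::lm(log(msd) ~ log(1:6)))
  got <- msd_fit(w2$x, w2$y)
  expect_equal(unname(got["msd_a"]), exp(unname(co[1])), tolerance = 1e-12)
  expect_equal(unname(got["msd_b"]), unname(co[2]), tolerance = 1e-12)
})

test_that("first passage times match the analytic straight-path values", {
  x <- 0:59
  f <- fpt_features(x, rep(0, 60), x)
  expect_equal(unname(f["fpt_mean_5m"]), 10)       # 5 s out + 5 s back
  expect_equal(unname(f["fpt_varlog_5m"]), 0)
  expect_equal(unname(f["fpt_loglog_slope"]), 1, tolerance = 1e-9)
  # a path that never leaves a 0.5 m cluster is fully censored at 5 m
  set.seed(27)
  xc <- 0.2 * cos(runif(40, -pi, pi)); yc <- 0.2 * sin(runif(40, -pi, pi))
  fc <- fpt_features(xc, yc, 0:39)
  expect_true(is.na(fc["fpt_mean_5m"]))
})

test_that("first passage times match a brute-force oracle on random paths", {
  w <- random_walk(50, step_sd = 1.5, seed = 28)
  fwd <- envmove:::fpt_exit_times(w$x, w$y, w$t, as.numeric(1:10), 1L)
  bwd <- envmove:::fpt_exit_times(w$x, w$y, w$t, as.numeric(1:10), -1L)
  for (r in c(1, 3, 5, 10)) {
    both <- vapply(seq_along(w$x), function(i)
      oracle_fpt_one(w$x, w$y, w$t, i, r), numeric(1))
    expect_equal(fwd[, r] + bwd[, r], both, tolerance = 1e-12)
  }
})

test_that("the 27-feature vector is rigid-motion invariant and deterministic", {
  expect_length(individual_feature_names(), 27)
  expect_length(individual_feature_names("window"), 24)
  w <- random_walk(120, seed = 29)
  v0 <- individual_gps_features(w$x, w$y, w$t)
  expect_length(v0, 27)
  expect_identical(v0, individual_gps_features(w$x, w$y, w$t))
  set.seed(30)
  for (i in 1:5) {
    th <- runif(1, -pi, pi); dx <- runif(1, -50, 50); dy <- runif(1, -50, 50)
    xr <- cos(th) * w$x - sin(th) * w$y + dx
    yr <- sin(th) * w$x + cos(th) * w$y + dy
    vr <- individual_gps_features(xr, yr, w$t)
    expect_equal(v0, vr, tolerance = 1e-9)
  }
})

test_that("an hour of straight-line travel hits the ballistic limits", {
  x <- 0:3599
  v <- individual_gps_features(x, rep(0, 3600), x)
  expect_equal(unname(v["spd_mean"]), 1)
  expect_equal(unname(v["spd_sd"]), 0)
  expect_equal(unname(v["ngr"]), 1)
  expect_equal(unname(v["turn_rho"]), 1)
  expect_equal(unname(v["msd_b"]), 2, tolerance = 1e-9)
  expect_equal(unname(v["fpt_loglog_slope"]), 1, tolerance = 1e-9)
})
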