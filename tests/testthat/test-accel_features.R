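# Independent re-implementation of the 21 geometric channels, coded directly
# from the channel definitions (scalar, norm/cross based) as the oracle.
oracle_channels <- function(x, y, z) {
  nrm <- function(v) sqrt(sum(v^2))
  ang <- function(num, den) if (num == 0 && den == 0) NA_real_ else atan2(num, den)
  sol <- function(num, d1, d2) {
    den <- nrm(d1) * nrm(d2)
    if (den == 0) return(NA_real_)
    asin(max(-1, min(1, num / den)))
  }
  cr <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                         a[3] * b[1] - a[1] * b[3],
                         a[1] * b[2] - a[2] * b[1])
  c(
    x = x, y = y, z = z,
    r_xyz = nrm(c(x, y, z)), r_xy = nrm(c(x, y)), r_xz = nrm(c(x, z)),
    r_yz = nrm(c(y, z)),
    theta_xy = ang(y, x), theta_xz = ang(z, x), theta_yz = ang(z, y),
    theta_z = ang(z, nrm(c(x, y))), theta_y = ang(y, nrm(c(x, z))),
    theta_x = ang(x, nrm(c(y, z))),
    omega_x = sol(y * z, c(x, y, 0), c(x, 0, z)),
    omega_y = sol(x * z, c(x, y, 0), c(0, y, z)),
    omega_z = sol(x * y, c(x, 0, z), c(0, y, z)),
    v_xyz = x * y * z,
    a_x = y * z, a_y = x * z, a_z = x * y,
    a_xyz = 0.5 * nrm(cr(c(x, y, 0), c(x, 0, z)))
  )
}

test_that("geometric transform reproduces worked examples", {
  g <- geometric_transform(1, 1, 1)[1, ]
  expect_equal(unname(g["r_xyz"]), sqrt(3))
  expect_equal(unname(g["theta_xy"]), pi / 4)
  expect_equal(unname(g["omega_z"]), pi / 6)
  expect_equal(unname(g["v_xyz"]), 1)
  expect_equal(unname(g["a_xyz"]), sqrt(3) / 2)

  g2 <- geometric_transform(3, 4, 0)[1, ]
  expect_equal(unname(g2[c("r_xy", "r_xyz", "v_xyz", "a_z")]), c(5, 5, 0, 12))

  g3 <- geometric_transform(1, 0, 0)[1, ]
  expect_equal(unname(g3["theta_xy"]), 0)
  expect_true(is.na(g3["omega_z"]))  # zero resultant in the y,z plane
  expect_equal(unname(g3[c("v_xyz", "a_x", "a_y", "a_z", "a_xyz")]), rep(0, 5))
})

test_that("all 21 channels match the independent formula oracle on random input", {
  set.seed(10)
  n <- 1000
  ax <- rnorm(n); ay <- rnorm(n); az <- rnorm(n)
  got <- geometric_transform(ax, ay, az)
  expect_equal(ncol(got), 21)
  expect_identical(colnames(got), accel_channels())
  ref <- t(vapply(seq_len(n), function(i) oracle_channels(ax[i], ay[i], az[i]),
                  numeric(21)))
  attr(got, "n_clamped") <- NULL
  expect_equal(unname(got), unname(ref), tolerance = 1e-9)
})

test_that("channels scale consistently under positive scaling of the axes", {
  set.seed(11)
  ax <- rnorm(50); ay <- rnorm(50); az <- rnorm(50)
  c0 <- geometric_transform(ax, ay, az)
  c3 <- geometric_transform(3 * ax, 3 * ay, 3 * az)
  r_cols <- c("x", "y", "z", "r_xyz", "r_xy", "r_xz", "r_yz")
  ang_cols <- grep("^theta|^omega", accel_channels(), value = TRUE)
  a_cols <- c("a_x", "a_y", "a_z", "a_xyz")
  expect_equal(c3[, r_cols], 3 * c0[, r_cols], tolerance = 1e-12)
  expect_equal(c3[, ang_cols], c0[, ang_cols], tolerance = 1e-9)
  expect_equal(c3[, a_cols], 9 * c0[, a_cols], tolerance = 1e-9)
  expect_equal(c3[, "v_xyz"], 27 * c0[, "v_xyz"], tolerance = 1e-9)
})

test_that("window statistics match the discrete-Fourier oracle", {
  # constant series: only the DC bin is populated
  ws <- window_statistics(rep(2, 96), duration_s = 3)
  expect_equal(unname(ws["mean"]), 2)
  expect_equal(unname(ws["sd"]), 0)
  expect_equal(unname(ws[c("min", "q1", "median", "q3", "max")]), rep(2, 5))
  expect_equal(unname(ws["dom_amp"]), 0)
  expect_equal(unname(ws["spec_energy"]), (96 * 2)^2)
  expect_true(is.na(ws["dom_period_s"]))

  # 4 Hz sine over 3 s at 32 Hz: dominant bin 12 -> period 0.25 s
  t <- (0:95) / 32
  ws2 <- window_statistics(sin(2 * pi * 4 * t), duration_s = 3)
  expect_equal(unname(ws2["dom_period_s"]), 0.25)

  # all-zero series: zero stats, undefined dominant period
  ws3 <- window_statistics(rep(0, 96), duration_s = 3)
  expect_equal(unname(ws3["spec_energy"]), 0)
  expect_true(is.na(ws3["dom_period_s"]))

  expect_true(all(is.na(window_statistics(rep(NA_real_, 10)))))
})

test_that("spectral energy obeys Parseval's identity for the unnormalized DFT", {
  set.seed(12)
  for (n in c(32, 96, 97)) {
    x <- rnorm(n)
    ws <- window_statistics(x, duration_s = n / 32)
    expect_equal(unname(ws["spec_energy"]), n * sum(x^2), tolerance = 1e-6)
  }
})

test_that("feature matrix has 210 stable columns and 1200 rows per hour", {
  expect_equal(length(accel_feature_names()), 210)
  set.seed(13)
  t <- seq(0, 3600 - 1 / 32, by = 1 / 32)
  acc <- data.frame(t = t, ax = sin(2 * pi * 1.2 * t) + rnorm(length(t), 0, 0.2),
                    ay = rnorm(length(t), 0, 0.3), az = 9.5 + rnorm(length(t), 0, 0.2))
  w <- make_windows(0, 3600, 3)
  F <- accel_feature_matrix(acc, w)
  expect_equal(dim(F), c(1200, 210))
  expect_identical(colnames(F), accel_feature_names())
  # quantile ordering and non-negative spread per channel
  for (ch in c("x", "r_xyz", "a_xyz")) {
    expect_true(all(F[, paste0(ch, "__min")] <= F[, paste0(ch, "__q1")]))
    expect_true(all(F[, paste0(ch, "__q1")] <= F[, paste0(ch, "__median")]))
    expect_true(all(F[, paste0(ch, "__median")] <= F[, paste0(ch, "__q3")]))
    expect_true(all(F[, paste0(ch, "__q3")] <= F[, paste0(ch, "__max")]))
    expect_true(all(F[, paste0(ch, "__sd")] >= 0))
    expect_true(all(F[, paste0(ch, "__spec_energy")] >= 0))
  }
})

test_that("identical windows give identical feature rows and sparse windows go missing", {
  set.seed(14)
  one <- data.frame(t = (0:95) / 32, ax = rnorm(96), ay = rnorm(96), az = rnorm(96))
  two <- rbind(one, transform(one, t = t + 3))
  w <- make_windows(0, 6, 3)
  F <- accel_feature_matrix(two, w)
  expect_equal(F[1, ], F[2, ])

  # second window holds <50% of expected samples -> all-missing row
  sparse <- rbind(one, data.frame(t = 3 + (0:20) / 32, ax = 1, ay = 1, az = 1))
  expect_message(F2 <- accel_feature_matrix(sparse, w), "quorum")
  expect_true(all(is.na(F2[2, ])))
  expect_false(anyNA(F2[1, grep("__mean$", colnames(F2))]))
})
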