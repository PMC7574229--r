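test_that("the hourly manifest enumerates 548 columns in the documented sets", {
  man <- hourly_variable_manifest()
  expect_equal(nrow(man), 548)
  expect_equal(anyDuplicated(man$column), 0)
  sizes <- table(man$set)[unique(man$set)]
  expect_equal(unname(as.integer(sizes)),
               c(27, 5, 4, 11, 11, 24, 24, 11, 11, 210, 210))
  expect_equal(sum(man$family == "ACC"), 420)
  expect_true(all(man$family %in% c("GPS", "ACC")))
})

# A fully synthetic animal-hour where every window is grazing and the
# trajectory is a straight line, so conditioning on grazing is a no-op.
make_synthetic_hour <- function(seed = 60, all_grazing = TRUE) {
  set.seed(seed)
  nw <- 1200
  acc <- matrix(rnorm(nw * 210), nw, 210, dimnames = list(NULL, accel_feature_names()))
  ind <- matrix(rnorm(nw * 27), nw, 27,
                dimnames = list(NULL, individual_feature_names()))
  ind[, "spd_median"] <- exp(rnorm(nw, -1, 0.2))
  ind[, "tv_median"] <- exp(rnorm(nw, -2, 0.3))
  grp <- matrix(rnorm(nw * 11), nw, 11, dimnames = list(NULL, group_feature_names()))
  lab <- data.frame(
    main_class = if (all_grazing) rep("grazing", nw) else
      sample(c("grazing", "walking", "standing", "lying"), nw, replace = TRUE),
    ruminating = rep(FALSE, nw)
  )
  x <- 0:3599
  list(x = x, y = rep(0, 3600), t = x, acc = acc, ind = ind, grp = grp, lab = lab)
}

test_that("an assembled hour has exactly 548 named values", {
  h <- make_synthetic_hour(all_grazing = FALSE)
  row <- assemble_hourly_row(h$x, h$y, h$t, h$acc, h$ind, h$grp, h$lab)
  expect_length(row, 548)
  expect_identical(names(row), hourly_variable_manifest()$column)
  props <- row[paste0("prop__", c("grazing", "walking", "standing", "lying"))]
  expect_equal(sum(props), 1)
})

test_that("conditioning on grazing is the identity when every window is grazing", {
  h <- make_synthetic_hour(all_grazing = TRUE)
  row <- assemble_hourly_row(h$x, h$y, h$t, h$acc, h$ind, h$grp, h$lab)
  expect_equal(unname(row["prop__grazing"]), 1)
  # grazing-conditional group block equals the unconditional one
  expect_equal(unname(row[paste0("grpgmed__", group_feature_names())]),
               unname(row[paste0("grpmed__", group_feature_names())]))
  # hour-level trajectory block reflects the straight-line path
  expect_equal(unname(row["indh__spd_mean"]), 1)
  expect_equal(unname(row["indh__ngr"]), 1)
  # log-distribution block matches direct computation
  expect_equal(unname(row["glog__speed_mean"]), mean(log(h$ind[, "spd_median"])))
  expect_equal(unname(row["glog__speed_sd"]), sd(log(h$ind[, "spd_median"])))
})

test_that("an hour with no grazing window leaves the conditional blocks missing", {
  h <- make_synthetic_hour(all_grazing = FALSE)
  h$lab$main_class <- rep(c("walking", "standing", "lying"), length.out = 1200)
  row <- assemble_hourly_row(h$x, h$y, h$t, h$acc, h$ind, h$grp, h$lab)
  expect_true(all(is.na(row[grep("^accgmed__|^accgsd__|^glog__", names(row))])))
  expect_false(anyNA(row[grep("^grpmed__", names(row))]))
})

test_that("day/night standardization fits on training rows and imputes zeros", {
  set.seed(61)
  cols <- hourly_variable_manifest()$column
  n <- 40
  rec <- data.frame(animal_id = rep(c("c1", "c2"), each = n / 2),
                    day_night = rep(c("day", "night"), n / 2))
  M <- matrix(rnorm(n * 548, 5, 2), n, 548, dimnames = list(NULL, cols))
  M[1, 3] <- NA            # a missing cell
  M[, 10] <- 7             # a constant column
  rec <- cbind(rec, as.data.frame(M, check.names = FALSE))
  train <- 1:n
  std <- standardize_day_night(rec, train = train)
  Z <- as.matrix(std$records[, cols])
  cells <- interaction(rec$animal_id, rec$day_night)
  for (cell in levels(cells)) {
    i <- which(cells == cell)
    expect_equal(unname(colMeans(Z[i, -c(3, 10)])), rep(0, 546), tolerance = 1e-9)
    expect_equal(unname(apply(Z[i, -c(3, 10)], 2, var)), rep(1, 546),
                 tolerance = 1e-9)
  }
  expect_true(all(Z[, 10] == 0))        # constant column -> zeros
  expect_equal(as.numeric(Z[1, 3]), 0)  # imputed at the cell mean
  expect_gte(std$n_imputed, 1)
})

test_that("test rows are standardized with training parameters, not their own", {
  set.seed(62)
  cols <- hourly_variable_manifest()$column
  rec <- data.frame(animal_id = "c1", day_night = "day")[rep(1, 30), ]
  M <- matrix(rnorm(30 * 548), 30, 548, dimnames = list(NULL, cols))
  rec <- cbind(rec, as.data.frame(M, check.names = FALSE))
  std <- standardize_day_night(rec, train = 1:20)
  mu <- colMeans(M[1:20, ]); sg <- apply(M[1:20, ], 2, sd)
  expected <- (M[25, ] - mu) / sg
  expect_equal(unname(as.numeric(std$records[25, cols])), unname(expected),
               tolerance = 1e-9)
  # mutating held-out rows leaves the parameters unchanged
  rec2 <- rec
  rec2[21:30, cols] <- rec2[21:30, cols] * 10
  std2 <- standardize_day_night(rec2, train = 1:20)
  expect_equal(std$params, std2$params)
})

test_that("family projections capture planted low-rank structure", {
  set.seed(63)
  man <- hourly_variable_manifest()
  cols <- man$column
  n <- 30
  rec <- data.frame(animal_id = "c1", day_night = "day")[rep(1, n), ]
  # GPS family of true rank 3
  gcols <- man$column[man$family == "GPS"]
  basis <- matrix(rnorm(3 * length(gcols)), 3)
  scores <- matrix(rnorm(n * 3), n)
  M <- matrix(rnorm(n * 548, 0, 1e-8), n, 548, dimnames = list(NULL, cols))
  M[, gcols] <- scores %*% basis
  rec <- cbind(rec, as.data.frame(M, check.names = FALSE))
  proj <- fit_family_projection(rec, "GPS", 3)
  expect_equal(sum(proj$explained[1:3]), 1, tolerance = 1e-6)
  S <- project_family(proj, rec)
  expect_equal(dim(S), c(n, 3))
  cc <- cor(S)
  expect_true(all(abs(cc[upper.tri(cc)]) < 1e-6))
  expect_identical(S, project_family(proj, rec))
  expect_warning(fit_family_projection(rec[1:5, ], "GPS", 10), "truncated")
})

test_that("environmental targets are hourly means with sawtooth handling", {
  # hour with linear biomass decline 1000 -> 990 and constant wind 3
  t0 <- 1493103600  # a 09:00 local hour
  tt <- seq(t0, t0 + 3599, by = 60)
  frac <- (tt - t0) / 3600
  env <- data.frame(t = tt, biomass = 1000 - 10 * frac,
                    time_since_milking = ifelse(frac < 0.5, 1 + frac, frac - 0.5),
                    wind = 3, session_id = "S1")
  rec <- data.frame(animal_id = "c1", hour = hour_key(t0 + 1800))
  out <- attach_env_targets(rec, env)
  expect_equal(out$biomass, mean(env$biomass))
  expect_equal(out$biomass, 995, tolerance = 0.1)
  expect_equal(out$wind, 3)
  # sawtooth resetting mid-hour: mean of the two ramps (piecewise integration)
  fine <- function(f) mean(ifelse(f < 0.5, 1 + f, f - 0.5))
  expect_equal(out$time_since_milking, fine(frac), tolerance = 1e-9)
  expect_equal(out$session_id, "S1")
  # an hour with no coverage is dropped
  rec2 <- data.frame(animal_id = "c1", hour = hour_key(t0 + 1800) + 500)
  expect_message(out2 <- attach_env_targets(rbind(rec, rec2), env), "dropped")
  expect_equal(nrow(out2), 1)
})
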