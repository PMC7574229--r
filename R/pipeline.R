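# End-to-end orchestration: raw sensor streams -> per-window features ->
# activity labels -> hourly variable sets -> environmental influence.

# Design matrix of one animal-hour's windows for the activity classifier:
# the 210 accelerometer features plus the 24-feature per-window individual
# GPS block.
.window_design_matrix <- function(acc_feat, ind_feat) {
  ind24 <- individual_feature_names("window")
  cbind(acc_feat, ind_feat[, ind24, drop = FALSE])
}

# Observed activity label per window (at the window midpoint) from an
# ethogram interval table of one animal.
.observed_labels <- function(itv, windows) {
  mid <- (windows$start + windows$end) / 2
  out <- data.frame(main_class = rep(NA_character_, nrow(windows)),
                    ruminating = rep(NA, nrow(windows)))
  if (is.null(itv) || nrow(itv) == 0L) return(out)
  o <- order(itv$start)
  itv <- itv[o, ]
  i <- findInterval(mid, itv$start)
  ok <- i >= 1L & mid < itv$end[pmax(i, 1L)]
  out$main_class[ok] <- as.character(itv$main_class[i[ok]])
  out$ruminating[ok] <- itv$ruminating[i[ok]]
  out
}

# Per-window individual GPS features of one animal-hour. Windows holding
# exactly three 1 Hz fixes (the typical 3 s case) go through a vectorized
# closed-form path; anything else falls back to the generic per-window
# computation. Both paths agree to floating point (see tests).
.window_ind_features <- function(pos, windows) {
  nw <- nrow(windows)
  out <- matrix(NA_real_, nw, 27L,
                dimnames = list(windows$index, individual_feature_names()))
  if (nrow(pos) == 0L) return(out)
  tnum <- as.numeric(pos$t)
  wi <- assign_windows(tnum, windows)
  keep <- which(!is.na(wi))
  cnt <- tabulate(wi[keep], nbins = nw)
  fast <- which(cnt == 3L)
  if (length(fast)) {
    ord <- keep[order(wi[keep])]
    ord <- ord[wi[ord] %in% fast]
    X <- matrix(pos$x[ord], nrow = 3L)
    Y <- matrix(pos$y[ord], nrow = 3L)
    Tm <- matrix(tnum[ord], nrow = 3L)
    out[fast, ] <- .ind3_closed_form(X, Y, Tm)
    slow <- setdiff(which(cnt >= 2L), fast)
  } else {
    slow <- which(cnt >= 2L)
  }
  for (w in slow) {
    rows <- keep[wi[keep] == w]
    out[w, ] <- individual_gps_features(pos$x[rows], pos$y[rows], tnum[rows])
  }
  out
}

# Closed-form 27-feature block for three-fix windows (columns = windows).
.ind3_closed_form <- function(X, Y, Tm) {
  k <- ncol(X)
  dt1 <- Tm[2, ] - Tm[1, ]; dt2 <- Tm[3, ] - Tm[2, ]
  dx1 <- X[2, ] - X[1, ]; dx2 <- X[3, ] - X[2, ]
  dy1 <- Y[2, ] - Y[1, ]; dy2 <- Y[3, ] - Y[2, ]
  l1 <- sqrt(dx1^2 + dy1^2); l2 <- sqrt(dx2^2 + dy2^2)
  s1 <- l1 / dt1; s2 <- l2 / dt2
  lo <- pmin(s1, s2); hi <- pmax(s1, s2)
  gross <- l1 + l2
  net <- sqrt((X[3, ] - X[1, ])^2 + (Y[3, ] - Y[1, ])^2)
  # Brownian scaling with two increments
  mx <- (dx1 / dt1 + dx2 / dt2) / 2
  my <- (dy1 / dt1 + dy2 / dt2) / 2
  cxx <- (dx1 / sqrt(dt1) - mx)^2 + (dx2 / sqrt(dt2) - mx)^2
  cyy <- (dy1 / sqrt(dt1) - my)^2 + (dy2 / sqrt(dt2) - my)^2
  bms <- sqrt((cxx + cyy) / 4)
  # single turning angle: defined iff both steps move
  moved <- l1 > 0 & l2 > 0
  rho <- ifelse(moved, 1, NA_real_)
  # single tangential velocity from the circumradius of the triple
  K <- 0.5 * abs(dx1 * dy2 - dx2 * dy1)
  cc <- net
  Rc <- ifelse(K > 0, l1 * l2 * cc / (4 * K), NA_real_)
  h1 <- atan2(dy1, dx1); h2 <- atan2(dy2, dx2)
  dth <- .wrap_angle(h2 - h1)
  dt_mid <- (Tm[3, ] - Tm[1, ]) / 2
  tv <- ifelse(moved, abs(dth / dt_mid) * Rc, NA_real_)
  # FPT: only meaningful when the in-window path can leave the 1 m circle
  fpt <- matrix(NA_real_, 5L, k)
  cand <- which(gross >= 1)
  for (j in cand) {
    fpt[, j] <- fpt_features(X[, j], Y[, j], Tm[, j])
  }
  res <- rbind(
    ngr = ifelse(gross > 0, net / gross, NA_real_),
    spd_mean = (s1 + s2) / 2,
    spd_sd = abs(s1 - s2) / sqrt(2),
    spd_median = (lo + hi) / 2,
    spd_min = lo,
    spd_max = hi,
    spd_q1 = lo + 0.25 * (hi - lo),
    spd_q3 = lo + 0.75 * (hi - lo),
    spd_acf1 = NA_real_,
    spd_bms = bms,
    turn_rho = rho,
    turn_abs_acf1 = NA_real_,
    tv_mean = tv, tv_sd = NA_real_, tv_median = tv, tv_min = tv,
    tv_max = tv, tv_q1 = tv, tv_q3 = tv, tv_acf1 = NA_real_,
    msd_a = NA_real_, msd_b = NA_real_,
    fpt_mean_5m = fpt[1, ], fpt_varlog_5m = fpt[2, ], fpt_acf1_5m = fpt[3, ],
    fpt_argmax_var_radius = fpt[4, ], fpt_loglog_slope = fpt[5, ]
  )
  t(res)[, individual_feature_names(), drop = FALSE]
}

#' Build the hourly movement dataset from sensor streams
#'
#' Runs the full per-window feature extraction (accelerometer, individual
#' GPS, group GPS), labels each 3 s window with an activity (observed from an
#' ethogram, or predicted by a fitted activity model), and assembles the 548
#' hourly movement variables per animal-hour.
#'
#' @param fixes_xy projected, HDOP-filtered GPS fixes (`animal_id`, `t`,
#'   `x`, `y`) at 1 Hz.
#' @param accel_provider function `(animal_id, t0)` returning that cow-hour's
#'   uniform 32 Hz samples (`t`, `ax`, `ay`, `az`), or `NULL` when absent.
#'   Use [sim_accel()] for simulations or a closure over a resampled frame
#'   for CSV data.
#' @param activities observed ethogram intervals (required when
#'   `activity_model` is `NULL`).
#' @param activity_model optional fitted [fit_activity_model()] model; when
#'   given, window labels are its predictions (the production configuration:
#'   activity sets use the classifier output).
#' @param window_s window length in seconds (default 3).
#' @param utc_offset_h local clock offset (default 2).
#' @param min_window_frac minimum fraction of labelled, feature-complete
#'   windows for an hour to contribute (default 0.5).
#' @param verbose print per-hour progress.
#' @return Data frame: `animal_id`, `hour` (local hour key), `t0` (epoch
#'   start), `day_night`, plus the 548 movement columns.
#' @export
build_hourly_dataset <- function(fixes_xy, accel_provider, activities = NULL,
                                 activity_model = NULL, window_s = 3,
                                 utc_offset_h = 2, min_window_frac = 0.5,
                                 verbose = FALSE) {
  if (is.null(activities) && is.null(activity_model)) {
    stop("either observed 'activities' or a fitted 'activity_model' is required")
  }
  hk <- hour_key(fixes_xy$t, utc_offset_h)
  hours <- sort(unique(hk))
  ids <- sort(unique(fixes_xy$animal_id))
  act_by_id <- if (!is.null(activities)) split(activities, activities$animal_id)
  rows <- list()
  nw_expected <- floor(3600 / window_s)
  for (h in hours) {
    t0 <- h * 3600 - utc_offset_h * 3600
    ph <- fixes_xy[hk == h, , drop = FALSE]
    windows <- make_windows(t0, t0 + 3600, window_s)
    grp <- group_feature_windows(ph, windows)
    for (id in ids) {
      pos <- ph[ph$animal_id == id, , drop = FALSE]
      if (nrow(pos) < 2L) next
      acc <- accel_provider(id, t0)
      if (is.null(acc)) next
      acc_feat <- accel_feature_matrix(acc, windows)
      ind_feat <- .window_ind_features(pos, windows)
      if (!is.null(activity_model)) {
        X <- .window_design_matrix(acc_feat, ind_feat)
        ok <- rowSums(is.finite(acc_feat)) > 0L
        lab <- data.frame(main_class = rep(NA_character_, nrow(windows)),
                          ruminating = rep(NA, nrow(windows)))
        if (any(ok)) {
          pr <- predict(activity_model, X[ok, , drop = FALSE])
          lab$main_class[ok] <- pr$main_class
          lab$ruminating[ok] <- pr$ruminating
        }
      } else {
        lab <- .observed_labels(act_by_id[[id]], windows)
      }
      n_valid <- sum(!is.na(lab$main_class) & rowSums(is.finite(acc_feat)) > 0L)
      if (n_valid < min_window_frac * nw_expected) next
      g_id <- if (id %in% dimnames(grp)[[2]]) grp[, id, ] else
        matrix(NA_real_, nrow(windows), 11L,
               dimnames = list(NULL, group_feature_names()))
      row <- assemble_hourly_row(pos$x, pos$y, as.numeric(pos$t),
                                 acc_feat, ind_feat, g_id, lab)
      rows[[length(rows) + 1L]] <- c(
        list(animal_id = id, hour = h, t0 = t0,
             day_night = day_night(t0 + 1800, utc_offset_h = utc_offset_h)),
        as.list(row)
      )
    }
    if (verbose) message(sprintf("hour %d: %d record(s) so far", h, length(rows)))
  }
  if (length(rows) == 0L) {
    stop("no animal-hour met the window quorum")
  }
  out <- do.call(rbind, lapply(rows, function(r) as.data.frame(r, check.names = FALSE)))
  rownames(out) <- NULL
  out
}

#' Assemble an activity-classification training set
#'
#' Extracts the per-window design matrix (accelerometer + individual GPS
#' block) and the observed ethogram labels for the given hours.
#'
#' @inheritParams build_hourly_dataset
#' @param hours local hour keys to include (default: all hours with fixes).
#' @return List with `features` (matrix), `main_class`, `ruminating`,
#'   `hour_keys` and `window_t0` per labelled window.
#' @export
build_activity_training <- function(fixes_xy, accel_provider, activities,
                                    hours = NULL, window_s = 3,
                                    utc_offset_h = 2) {
  hk <- hour_key(fixes_xy$t, utc_offset_h)
  if (is.null(hours)) hours <- sort(unique(hk))
  ids <- sort(unique(fixes_xy$animal_id))
  act_by_id <- split(activities, activities$animal_id)
  feats <- list(); labs <- list()
  for (h in hours) {
    t0 <- h * 3600 - utc_offset_h * 3600
    ph <- fixes_xy[hk == h, , drop = FALSE]
    if (nrow(ph) == 0L) next
    windows <- make_windows(t0, t0 + 3600, window_s)
    for (id in ids) {
      pos <- ph[ph$animal_id == id, , drop = FALSE]
      acc <- accel_provider(id, t0)
      if (is.null(acc) || nrow(pos) < 2L) next
      acc_feat <- accel_feature_matrix(acc, windows)
      ind_feat <- .window_ind_features(pos, windows)
      lab <- .observed_labels(act_by_id[[id]], windows)
      ok <- !is.na(lab$main_class) & rowSums(is.finite(acc_feat)) > 0L
      if (!any(ok)) next
      feats[[length(feats) + 1L]] <- .window_design_matrix(acc_feat, ind_feat)[ok, , drop = FALSE]
      labs[[length(labs) + 1L]] <- data.frame(
        main_class = lab$main_class[ok], ruminating = lab$ruminating[ok],
        hour = h, t0 = windows$start[ok]
      )
    }
  }
  if (length(feats) == 0L) stop("no labelled windows found")
  lab <- do.call(rbind, labs)
  list(
    features = do.call(rbind, feats),
    main_class = lab$main_class,
    ruminating = lab$ruminating,
    hour_keys = lab$hour,
    window_t0 = lab$t0
  )
}

#' Quantify the environmental influence on movement
#'
#' The core analysis: standardize the hourly movement variables per
#' day/night and animal (training parameters only), project each sensor
#' family onto principal components fitted on the training sessions, fit the
#' regression backend on the combined, GPS-only and accelerometer-only
#' component sets, score each with the held-out-session coefficient of
#' determination, and partition the combined explained variation into
#' independent and shared components.
#'
#' @param records hourly records ([build_hourly_dataset()]) with targets
#'   attached ([attach_env_targets()]).
#' @param target `"biomass"`, `"time_since_milking"` or `"wind"` (any target
#'   column).
#' @param test_session session id held out for testing.
#' @param config a [regressor_config()]; its `families` field is ignored
#'   (all three family sets are fitted).
#' @param n_components named vector of components per family,
#'   e.g. `c(GPS = 12, ACC = 12)`.
#' @return List of class `influence_analysis`: `influence` (test R-squared of
#'   the combined model), `partition`, per-family `results`, `projections`
#'   and the split.
#' @export
quantify_influence <- function(records, target, test_session,
                               config = regressor_config(),
                               n_components = c(GPS = 12L, ACC = 12L)) {
  split <- session_split(records, test_session, target)
  std <- standardize_day_night(records, train = split$train)
  projs <- list(
    GPS = fit_family_projection(std$records, "GPS", n_components[["GPS"]],
                                train = split$train),
    ACC = fit_family_projection(std$records, "ACC", n_components[["ACC"]],
                                train = split$train)
  )
  SG <- project_family(projs$GPS, std$records)
  SA <- project_family(projs$ACC, std$records)
  y <- records[[target]]
  sets <- list(GPS = SG, ACC = SA, combined = cbind(SG, SA))
  results <- lapply(sets, function(S) {
    fit_and_score(S[split$train, , drop = FALSE], y[split$train],
                  S[split$test, , drop = FALSE], y[split$test], config)
  })
  part <- partition_variation(results$ACC$r2_test, results$GPS$r2_test,
                              results$combined$r2_test)
  structure(list(
    target = target, influence = results$combined$r2_test,
    partition = part, results = results, projections = projs,
    split = split, config = config
  ), class = "influence_analysis")
}

#' @export
print.influence_analysis <- function(x, ...) {
  cat(sprintf("Environmental influence on movement: target '%s'\n", x$target))
  cat(sprintf("  combined R2 (influence): %.3f\n", x$influence))
  cat(sprintf("  GPS-only R2: %.3f   ACC-only R2: %.3f\n",
              x$results$GPS$r2_test, x$results$ACC$r2_test))
  p <- x$partition
  cat(sprintf("  partition: shared %.3f, independent GPS %.3f, independent ACC %.3f\n",
              p[["shared"]], p[["independent_gps"]], p[["independent_acc"]]))
  invisible(x)
}
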