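# Assembly of the per-animal, per-hour variable sets: 548 movement variables
# per animal-hour, built from the hour-level trajectory features, per-window
# activity predictions, and medians/standard deviations of the per-window
# feature blocks (several of them conditional on predicted grazing).

#' Manifest of the 548 hourly movement variables
#'
#' Enumerates every hourly column with its variable set and sensor family.
#' The per-set sizes (27, 5, 4, 11, 11, 24, 24, 11, 11, 210, 210) sum to 548.
#' The per-window individual GPS subset used in the grazing-conditional sets
#' has 24 features: the full 27 minus the two MSD power-law coefficients and
#' the Brownian scaling parameter, which are not estimable from the <= 4
#' fixes of a 3 s window.
#'
#' @return Data frame with columns `column`, `set`, `family` (`"GPS"` or
#'   `"ACC"`).
#' @export
hourly_variable_manifest <- function() {
  ind27 <- individual_feature_names()
  ind24 <- individual_feature_names("window")
  grp <- group_feature_names()
  acc <- accel_feature_names()
  blocks <- list(
    list("individual_gps_hourly", paste0("indh__", ind27), "GPS"),
    list("activity_proportion",
         paste0("prop__", c("grazing", "walking", "standing", "lying", "ruminating")),
         "GPS"),
    list("grazing_log_distribution",
         paste0("glog__", c("speed_mean", "speed_sd", "tv_mean", "tv_sd")), "GPS"),
    list("group_median", paste0("grpmed__", grp), "GPS"),
    list("group_sd", paste0("grpsd__", grp), "GPS"),
    list("ind_grazing_median", paste0("indgmed__", ind24), "GPS"),
    list("ind_grazing_sd", paste0("indgsd__", ind24), "GPS"),
    list("group_grazing_median", paste0("grpgmed__", grp), "GPS"),
    list("group_grazing_sd", paste0("grpgsd__", grp), "GPS"),
    list("accel_grazing_median", paste0("accgmed__", acc), "ACC"),
    list("accel_grazing_sd", paste0("accgsd__", acc), "ACC")
  )
  do.call(rbind, lapply(blocks, function(b) {
    data.frame(column = b[[2]], set = b[[1]], family = b[[3]])
  }))
}

# Column-wise median / sd over a subset of window rows, NA-tolerant.
.block_med_sd <- function(M, rows, prefix_med, prefix_sd) {
  if (length(rows) == 0L) {
    med <- rep(NA_real_, ncol(M)); sdv <- med
  } else {
    S <- M[rows, , drop = FALSE]
    med <- apply(S, 2L, stats::median, na.rm = TRUE)
    sdv <- apply(S, 2L, stats::sd, na.rm = TRUE)
    med[!is.finite(med)] <- NA_real_
    sdv[!is.finite(sdv)] <- NA_real_
  }
  c(stats::setNames(med, paste0(prefix_med, colnames(M))),
    stats::setNames(sdv, paste0(prefix_sd, colnames(M))))
}

#' Assemble the 548 movement variables of one animal-hour
#'
#' @param x,y,t 1 Hz projected positions of the focal animal over the hour.
#' @param acc_feat per-window accelerometer features (windows x 210,
#'   [accel_feature_matrix()]).
#' @param ind_feat per-window individual GPS features (windows x 27).
#' @param grp_feat per-window group features for the focal animal
#'   (windows x 11).
#' @param activity data frame with per-window `main_class` and `ruminating`
#'   (predicted, or observed for validation runs); `NA` rows are windows
#'   without a prediction.
#' @return Named numeric vector of length 548 in manifest order. Grazing-
#'   conditional blocks are `NA` when the hour has no grazing window (imputed
#'   downstream by the standardization step).
#' @export
assemble_hourly_row <- function(x, y, t, acc_feat, ind_feat, grp_feat, activity) {
  man <- hourly_variable_manifest()
  out <- stats::setNames(rep(NA_real_, nrow(man)), man$column)
  ind27 <- individual_feature_names()
  ind24 <- individual_feature_names("window")

  if (length(x) >= 2L) {
    hh <- individual_gps_features(x, y, t)
    out[paste0("indh__", ind27)] <- hh
  }
  pred <- !is.na(activity$main_class)
  if (any(pred)) {
    for (cl in c("grazing", "walking", "standing", "lying")) {
      out[paste0("prop__", cl)] <- mean(activity$main_class[pred] == cl)
    }
    out["prop__ruminating"] <- mean(activity$ruminating[pred], na.rm = TRUE)
  }
  g <- which(pred & activity$main_class == "grazing")

  logstat <- function(v) {
    v <- v[is.finite(v) & v > 0]
    if (length(v) == 0L) return(c(NA_real_, NA_real_))
    lv <- log(v)
    c(mean(lv), if (length(lv) > 1L) stats::sd(lv) else NA_real_)
  }
  if (length(g)) {
    sp <- logstat(ind_feat[g, "spd_median"])
    tv <- logstat(ind_feat[g, "tv_median"])
    out["glog__speed_mean"] <- sp[1]; out["glog__speed_sd"] <- sp[2]
    out["glog__tv_mean"] <- tv[1]; out["glog__tv_sd"] <- tv[2]
  }
  all_w <- seq_len(nrow(grp_feat))
  b1 <- .block_med_sd(grp_feat, all_w, "grpmed__", "grpsd__")
  b2 <- .block_med_sd(ind_feat[, ind24, drop = FALSE], g, "indgmed__", "indgsd__")
  b3 <- .block_med_sd(grp_feat, g, "grpgmed__", "grpgsd__")
  b4 <- .block_med_sd(acc_feat, g, "accgmed__", "accgsd__")
  for (b in list(b1, b2, b3, b4)) out[names(b)] <- b
  out
}

#' Standardize hourly records per day/night and animal
#'
#' Z-scores every movement column within each (animal, day/night) cell using
#' parameters estimated from the training rows only; missing values are then
#' imputed as 0 (the cell mean). Zero-variance columns standardize to 0.
#'
#' @param records data frame with `animal_id`, `day_night` and the movement
#'   columns.
#' @param columns movement column names (default: the manifest columns).
#' @param train integer/logical index of training rows used to fit the
#'   parameters (default: all rows).
#' @return List with `records` (standardized copy), `params` (per-cell means
#'   and sds) and `n_imputed`.
#' @export
standardize_day_night <- function(records, columns = NULL, train = NULL) {
  if (is.null(columns)) columns <- hourly_variable_manifest()$column
  if (is.null(train)) train <- seq_len(nrow(records))
  cells <- interaction(records$animal_id, records$day_night, drop = FALSE)
  params <- list()
  out <- records
  n_imputed <- 0L
  for (cell in unique(as.character(cells))) {
    rows <- which(as.character(cells) == cell)
    tr <- intersect(rows, if (is.logical(train)) which(train) else train)
    if (length(tr) == 0L) tr <- rows  # no training rows: fall back, flagged
    M <- as.matrix(records[tr, columns])
    mu <- colMeans(M, na.rm = TRUE)
    sg <- apply(M, 2L, stats::sd, na.rm = TRUE)
    mu[!is.finite(mu)] <- 0
    bad <- !is.finite(sg) | sg == 0
    sg[bad] <- Inf
    params[[cell]] <- list(mean = mu, sd = sg, n_train = length(tr))
    Z <- sweep(sweep(as.matrix(records[rows, columns]), 2L, mu, "-"), 2L, sg, "/")
    n_imputed <- n_imputed + sum(!is.finite(Z))
    Z[!is.finite(Z)] <- 0
    out[rows, columns] <- Z
  }
  list(records = out, params = params, n_imputed = n_imputed)
}

#' Fit a sensor-family principal-component projection
#'
#' @param records standardized hourly records (training rows only are used).
#' @param family `"GPS"` or `"ACC"`; selects the manifest columns of that
#'   sensor family.
#' @param n_components components to retain (truncated to the rank with a
#'   warning).
#' @param train row index of training records (default: all).
#' @return List of class `family_projection` with the rotation, explained
#'   variance shares and the column set.
#' @export
fit_family_projection <- function(records, family = c("GPS", "ACC"),
                                  n_components = 10L, train = NULL) {
  family <- match.arg(family)
  man <- hourly_variable_manifest()
  columns <- man$column[man$family == family]
  if (is.null(train)) train <- seq_len(nrow(records))
  M <- as.matrix(records[train, columns])
  pc <- stats::prcomp(M, center = TRUE, scale. = FALSE)
  rank <- sum(pc$sdev > pc$sdev[1] * 1e-12)
  if (n_components > rank) {
    warning(sprintf("n_components = %d exceeds rank %d; truncated", n_components, rank))
    n_components <- rank
  }
  structure(list(
    family = family, columns = columns, center = pc$center,
    rotation = pc$rotation[, seq_len(n_components), drop = FALSE],
    explained = pc$sdev^2 / sum(pc$sdev^2),
    n_components = n_components
  ), class = "family_projection")
}

#' Project hourly records onto fitted family components
#'
#' @param proj a [fit_family_projection()] object.
#' @param records standardized hourly records.
#' @return Numeric matrix (rows x components) named `<family>_PC<k>`.
#' @export
project_family <- function(proj, records) {
  M <- sweep(as.matrix(records[, proj$columns]), 2L, proj$center, "-")
  S <- M %*% proj$rotation
  colnames(S) <- paste0(proj$family, "_PC", seq_len(ncol(S)))
  S
}

#' Attach hourly environmental targets
#'
#' Per hour: mean grass biomass, mean time since milking and mean wind speed
#' over the environmental samples falling in the hour, plus the session id.
#' Hours with no environmental coverage are dropped with a message.
#'
#' @param records hourly records with an `hour` column (integer hour key).
#' @param env environmental series with `t`, `biomass`, `time_since_milking`,
#'   `wind`, `session_id`.
#' @param utc_offset_h local-clock offset used to key hours (default 2).
#' @return `records` with `biomass`, `time_since_milking`, `wind` and
#'   `session_id` columns appended.
#' @export
attach_env_targets <- function(records, env, utc_offset_h = 2) {
  hk <- hour_key(env$t, utc_offset_h)
  agg <- function(v) tapply(v, hk, mean)
  bio <- agg(env$biomass); tsm <- agg(env$time_since_milking); wind <- agg(env$wind)
  ses <- tapply(as.character(env$session_id), hk, function(s) names(sort(-table(s)))[1])
  i <- match(as.character(records$hour), names(bio))
  keep <- !is.na(i)
  if (any(!keep)) {
    message(sprintf("attach_env_targets: %d hour(s) without environmental coverage dropped",
                    sum(!keep)))
  }
  out <- records[keep, , drop = FALSE]
  i <- i[keep]
  out$biomass <- as.numeric(bio[i])
  out$time_since_milking <- as.numeric(tsm[i])
  out$wind <- as.numeric(wind[i])
  out$session_id <- as.character(ses[i])
  out
}
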