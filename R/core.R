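#' Filter GPS fixes by horizontal dilution of precision
#'
#' Removes fixes whose HDOP exceeds the threshold. The bound is strict: a fix
#' with HDOP exactly equal to the threshold is retained ("more than" the
#' threshold is untrustworthy).
#'
#' @param fixes data frame with at least an `hdop` column.
#' @param threshold positive HDOP cutoff; fixes with `hdop > threshold` are
#'   dropped. Default 5.
#' @return The retained fixes, in the original order.
#' @export
filter_hdop <- function(fixes, threshold = 5) {
  stopifnot(is.numeric(threshold), length(threshold) == 1L, threshold > 0)
  if (nrow(fixes) == 0L) return(fixes)
  fixes[fixes$hdop <= threshold, , drop = FALSE]
}

#' Split a timestamp vector into contiguous recording segments
#'
#' Collar tags commonly sleep for multi-hour periods to save battery, so a
#' stream of timestamps is a concatenation of contiguous segments. Any gap
#' larger than `gap_factor` times the nominal spacing starts a new segment;
#' windows never span segments.
#'
#' @param t numeric or POSIXct timestamps, non-decreasing.
#' @param nominal_dt nominal sample spacing in seconds (e.g., 1 for 1 Hz GPS).
#' @param gap_factor multiple of `nominal_dt` beyond which a gap splits the
#'   segment (default 2).
#' @return Integer vector of segment ids (1-based), same length as `t`.
#' @export
split_segments <- function(t, nominal_dt, gap_factor = 2) {
  n <- length(t)
  if (n == 0L) return(integer(0))
  dt <- diff(as.numeric(t))
  if (any(dt < 0)) stop("timestamps must be non-decreasing within a stream")
  cumsum(c(1L, as.integer(dt > gap_factor * nominal_dt)))
}

#' Resample an accelerometer stream to a constant rate
#'
#' Variable-rate tri-axial samples are down-sampled and linearly interpolated
#' to a uniform grid (default 32 Hz) within each contiguous segment. The grid
#' starts at the first timestamp of the segment and never extrapolates beyond
#' the last. Single-sample segments are dropped with a warning.
#'
#' @param samples data frame with columns `animal_id`, `t` (numeric seconds or
#'   POSIXct), `ax`, `ay`, `az`.
#' @param rate target rate in Hz (default 32).
#' @param nominal_dt nominal spacing of the *input* used for gap detection;
#'   default the per-animal median spacing.
#' @return Data frame with the same columns on a uniform `1/rate` grid, plus a
#'   `segment` column identifying contiguous runs.
#' @export
resample_accel <- function(samples, rate = 32, nominal_dt = NULL) {
  stopifnot(rate > 0)
  cols <- c("animal_id", "t", "ax", "ay", "az")
  stopifnot(all(cols %in% names(samples)))
  out <- list()
  dropped <- 0L
  for (id in unique(samples$animal_id)) {
    s <- samples[samples$animal_id == id, , drop = FALSE]
    s <- s[order(as.numeric(s$t)), , drop = FALSE]
    tn <- as.numeric(s$t)
    nd <- nominal_dt
    if (is.null(nd)) nd <- stats::median(diff(tn))
    seg <- split_segments(tn, nd)
    for (g in unique(seg)) {
      i <- which(seg == g)
      if (length(i) < 2L) {
        dropped <- dropped + 1L
        next
      }
      t0 <- tn[i[1]]; t1 <- tn[i[length(i)]]
      grid <- t0 + seq(0, floor((t1 - t0) * rate)) / rate
      out[[length(out) + 1L]] <- data.frame(
        animal_id = id,
        t = grid,
        ax = stats::approx(tn[i], s$ax[i], xout = grid)$y,
        ay = stats::approx(tn[i], s$ay[i], xout = grid)$y,
        az = stats::approx(tn[i], s$az[i], xout = grid)$y,
        segment = g
      )
    }
  }
  if (dropped > 0L) {
    warning(sprintf("%d single-sample segment(s) dropped during resampling", dropped))
  }
  if (length(out) == 0L) {
    return(data.frame(
      animal_id = character(0), t = numeric(0), ax = numeric(0),
      ay = numeric(0), az = numeric(0), segment = integer(0)
    ))
  }
  do.call(rbind, out)
}

#' Cut a contiguous segment into non-overlapping windows
#'
#' Windows start at the segment start; a trailing partial window is discarded.
#'
#' @param start,end segment span (numeric seconds or POSIXct).
#' @param duration_s window length in seconds (default 3).
#' @return Data frame with columns `index` (1-based ordinal), `start`, `end`;
#'   zero rows when the segment is shorter than one window.
#' @export
make_windows <- function(start, end, duration_s = 3) {
  stopifnot(duration_s > 0)
  span <- as.numeric(end) - as.numeric(start)
  k <- floor(span / duration_s + 1e-9)
  if (k < 1) {
    return(data.frame(index = integer(0), start = numeric(0), end = numeric(0)))
  }
  s0 <- as.numeric(start)
  idx <- seq_len(k)
  data.frame(index = idx, start = s0 + (idx - 1) * duration_s,
             end = s0 + idx * duration_s)
}

#' Assign samples to windows by half-open interval membership
#'
#' A sample at time `t` belongs to window `i` iff `start_i <= t < end_i`.
#'
#' @param t numeric or POSIXct sample times.
#' @param windows data frame from [make_windows()].
#' @return Integer window index per sample (`NA` outside all windows).
#' @export
assign_windows <- function(t, windows) {
  tn <- as.numeric(t)
  if (nrow(windows) == 0L) return(rep(NA_integer_, length(tn)))
  i <- findInterval(tn, windows$start)
  i[i < 1L] <- NA_integer_
  i[!is.na(i) & tn >= windows$end[pmax(i, 1L)]] <- NA_integer_
  i
}

#' Clock-hour key of a timestamp in local time
#'
#' Timestamps are carried internally as UTC; all clock-based logic (hour
#' blocking, day/night, milking times) runs in local time obtained by a fixed
#' UTC offset (default +2 h, central European summer time).
#'
#' @param t numeric seconds since epoch or POSIXct.
#' @param utc_offset_h hours to add to UTC (default 2).
#' @return Integer hour index (hours since epoch, local clock).
#' @export
hour_key <- function(t, utc_offset_h = 2) {
  as.integer(floor((as.numeric(t) + utc_offset_h * 3600) / 3600))
}

#' Day/night flag of a timestamp
#'
#' @param t numeric seconds since epoch or POSIXct.
#' @param day_start,day_end local clock hours bounding "day" (default 7 and
#'   19, i.e., day = \[07:00, 19:00)).
#' @param utc_offset_h hours to add to UTC (default 2).
#' @return Character vector `"day"` / `"night"`.
#' @export
day_night <- function(t, day_start = 7, day_end = 19, utc_offset_h = 2) {
  h <- (as.numeric(t) / 3600 + utc_offset_h) %% 24
  ifelse(h >= day_start & h < day_end, "day", "night")
}
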