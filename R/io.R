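# CSV readers/writers for the four input streams. One dialect throughout:
# comma-separated, header row, ISO-8601 UTC timestamps with fractional
# seconds where needed.

.parse_time <- function(x) {
  if (inherits(x, "POSIXct")) return(as.numeric(x))
  if (is.numeric(x)) return(as.numeric(x))
  as.numeric(as.POSIXct(x, format = "%Y-%m-%dT%H:%M:%OS", tz = "UTC"))
}

.format_time <- function(t) {
  format(as.POSIXct(as.numeric(t), origin = "1970-01-01", tz = "UTC"),
         "%Y-%m-%dT%H:%M:%OS3")
}

#' Read a GPS fix file
#'
#' Expected columns: `animal_id,t,lat,lon,hdop` with ISO-8601 timestamps.
#' Timestamps are returned as numeric seconds since the epoch (UTC).
#'
#' @param path CSV file path.
#' @return Data frame of fixes ordered by animal then time.
#' @export
read_gps_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("animal_id", "t", "lat", "lon", "hdop") %in% names(d)))
  d$t <- .parse_time(d$t)
  d[order(d$animal_id, d$t), , drop = FALSE]
}

#' @rdname read_gps_csv
#' @param fixes data frame of fixes to write.
#' @export
write_gps_csv <- function(fixes, path) {
  fixes$t <- .format_time(fixes$t)
  utils::write.csv(fixes, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a tri-axial accelerometer file
#'
#' Expected columns: `animal_id,t,ax,ay,az`.
#'
#' @param path CSV file path.
#' @return Data frame of samples ordered by animal then time.
#' @export
read_accel_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("animal_id", "t", "ax", "ay", "az") %in% names(d)))
  d$t <- .parse_time(d$t)
  d[order(d$animal_id, d$t), , drop = FALSE]
}

#' @rdname read_accel_csv
#' @param samples data frame of samples to write.
#' @export
write_accel_csv <- function(samples, path) {
  samples$t <- .format_time(samples$t)
  utils::write.csv(samples, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an ethogram annotation file
#'
#' Expected columns: `animal_id,start,end,main_class,ruminating`; classes are
#' the four mutually exclusive main activities (grazing, walking, standing,
#' lying) with rumination as a boolean overlay on standing/lying.
#'
#' @param path CSV file path.
#' @return Data frame of activity intervals.
#' @export
read_ethogram_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("animal_id", "start", "end", "main_class", "ruminating") %in% names(d)))
  d$start <- .parse_time(d$start)
  d$end <- .parse_time(d$end)
  bad <- setdiff(unique(d$main_class), c("grazing", "walking", "standing", "lying"))
  if (length(bad)) stop("unknown activity class(es): ", paste(bad, collapse = ", "))
  d$ruminating <- as.logical(d$ruminating)
  d[order(d$animal_id, d$start), , drop = FALSE]
}

#' @rdname read_ethogram_csv
#' @param intervals data frame of activity intervals to write.
#' @export
write_ethogram_csv <- function(intervals, path) {
  intervals$start <- .format_time(intervals$start)
  intervals$end <- .format_time(intervals$end)
  utils::write.csv(intervals, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an environmental series file
#'
#' Expected columns: `t,biomass,time_since_milking,wind,session_id` where
#' biomass is dry-matter grass biomass (kg DM per ha), time since milking is
#' in hours (a sawtooth resetting at milking events) and wind speed in m/s.
#'
#' @param path CSV file path.
#' @return Data frame ordered by time.
#' @export
read_env_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("t", "biomass", "time_since_milking", "wind", "session_id") %in% names(d)))
  d$t <- .parse_time(d$t)
  if (any(d$biomass < 0, na.rm = TRUE)) stop("biomass must be non-negative")
  if (any(d$time_since_milking < 0, na.rm = TRUE)) stop("time_since_milking must be non-negative")
  d[order(d$t), , drop = FALSE]
}

#' @rdname read_env_csv
#' @param env data frame of environmental records to write.
#' @export
write_env_csv <- function(env, path) {
  env$t <- .format_time(env$t)
  utils::write.csv(env, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
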