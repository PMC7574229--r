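# Group geometry per window and focal animal: neighbour distances and radius
# counts, group elongation, group area proxy, direction concentration, and a
# periphery index. All operate on the per-animal mean positions over the
# window ("group snapshot").

#' Names of the 11 group GPS features
#'
#' @return Character vector (prefix `grp__` is applied by callers that merge
#'   feature blocks).
#' @export
group_feature_names <- function() {
  c("nd_mean", "nd_median", "nd_min",
    "n_within_2m", "n_within_4m", "n_within_8m", "n_within_16m",
    "elongation_phi", "area_proxy", "direction_rho", "periphery_index")
}

#' Neighbour distance statistics for a focal animal
#'
#' Distances from the focal animal's snapshot position to every other
#' animal's, summarized as mean/median/minimum plus counts of animals within
#' 2, 4, 8 and 16 m (inclusive boundary).
#'
#' @param px,py numeric vectors of per-animal snapshot positions.
#' @param focal index of the focal animal.
#' @param radii count radii in metres (default `c(2, 4, 8, 16)`).
#' @return Named numeric vector of 7 values; all `NA` when fewer than two
#'   animals are present.
#' @export
neighbour_distance_stats <- function(px, py, focal, radii = c(2, 4, 8, 16)) {
  nm <- c("nd_mean", "nd_median", "nd_min",
          paste0("n_within_", radii, "m"))
  n <- length(px)
  if (n < 2L) return(stats::setNames(rep(NA_real_, length(nm)), nm))
  d <- sqrt((px[-focal] - px[focal])^2 + (py[-focal] - py[focal])^2)
  stats::setNames(
    c(mean(d), stats::median(d), min(d),
      vapply(radii, function(r) sum(d <= r), numeric(1))),
    nm
  )
}

# First-principal-component decomposition of the 2-D snapshot: explained
# share, sd of the PC1 scores. Closed form from the 2x2 covariance.
.snapshot_pca <- function(px, py) {
  n <- length(px)
  cx <- px - mean(px); cy <- py - mean(py)
  sxx <- sum(cx^2) / (n - 1)
  syy <- sum(cy^2) / (n - 1)
  sxy <- sum(cx * cy) / (n - 1)
  tr <- sxx + syy
  if (tr == 0) return(list(share = NA_real_, sd1 = NA_real_))
  disc <- sqrt(((sxx - syy) / 2)^2 + sxy^2)
  l1 <- tr / 2 + disc
  list(share = l1 / tr, sd1 = sqrt(l1))
}

#' Group elongation index
#'
#' Share of positional variance explained by the first principal component of
#' the snapshot coordinates, rescaled from \[0.5, 1\] to \[0, 1\]: 0 for a
#' perfectly non-elongated (circular) configuration, 1 when all animals are
#' collinear.
#'
#' @param px,py per-animal snapshot positions (at least 3 animals).
#' @return `phi` in \[0, 1\]; `NA` for identical positions or `n < 3`.
#' @export
elongation_index <- function(px, py) {
  if (length(px) < 3L) return(NA_real_)
  p <- .snapshot_pca(px, py)
  if (is.na(p$share)) return(NA_real_)
  2 * (p$share - 0.5)
}

#' Group area proxy
#'
#' `pi * sigma^2 * (1 - phi)` where `sigma` is the standard deviation of the
#' first-principal-component scores: the group is treated as an ellipse whose
#' area shrinks to 0 when fully elongated and equals `pi * sigma^2` when
#' circular.
#'
#' @inheritParams elongation_index
#' @return Area in square metres; `NA` as for [elongation_index()].
#' @export
group_area_proxy <- function(px, py) {
  if (length(px) < 3L) return(NA_real_)
  p <- .snapshot_pca(px, py)
  if (is.na(p$share)) return(NA_real_)
  phi <- 2 * (p$share - 0.5)
  pi * p$sd1^2 * (1 - phi)
}

#' Periphery index of a focal animal
#'
#' Directions from the focal animal to all others are sorted circularly; the
#' index is the largest gap between consecutive directions (including the
#' wrap-around gap) minus `2*pi/(n-1)`, divided by `2*pi`. Near 0 when the
#' focal animal is surrounded evenly; approaching `(n-2)/(n-1)` when all
#' neighbours lie in one direction.
#'
#' @inheritParams neighbour_distance_stats
#' @return Index value; `NA` when fewer than 2 distinct directions remain.
#' @export
periphery_index <- function(px, py, focal) {
  n <- length(px)
  if (n < 3L) return(NA_real_)
  dx <- px[-focal] - px[focal]
  dy <- py[-focal] - py[focal]
  keep <- !(dx == 0 & dy == 0)
  dirs <- sort(atan2(dy[keep], dx[keep]))
  if (length(dirs) < 2L) return(NA_real_)
  gaps <- c(diff(dirs), dirs[1] + 2 * pi - dirs[length(dirs)])
  (max(gaps) - 2 * pi / (n - 1)) / (2 * pi)
}

#' Direction concentration towards the other animals
#'
#' Mean resultant length of the directions from the focal animal to all
#' others: 0 when neighbours are spread evenly around, approaching 1 when
#' clustered in one direction.
#'
#' @inheritParams neighbour_distance_stats
#' @return Value in \[0, 1\].
#' @export
direction_rho <- function(px, py, focal) {
  n <- length(px)
  if (n < 2L) return(NA_real_)
  dx <- px[-focal] - px[focal]
  dy <- py[-focal] - py[focal]
  keep <- !(dx == 0 & dy == 0)
  if (!any(keep)) return(NA_real_)
  circular_rho(atan2(dy[keep], dx[keep]))
}

#' Group feature vector for one focal animal
#'
#' @inheritParams neighbour_distance_stats
#' @return Named numeric vector of 11 values ([group_feature_names()]).
#' @export
group_feature_vector <- function(px, py, focal) {
  c(
    neighbour_distance_stats(px, py, focal),
    elongation_phi = elongation_index(px, py),
    area_proxy = group_area_proxy(px, py),
    direction_rho = direction_rho(px, py, focal),
    periphery_index = periphery_index(px, py, focal)
  )[group_feature_names()]
}

#' Group features for all animals over a set of windows
#'
#' Builds per-window snapshots (window-mean position per animal) and the 11
#' group features per focal animal. Animals without GPS in a window are
#' excluded from that snapshot; the periphery normalization uses the count of
#' animals present.
#'
#' @param positions data frame with columns `animal_id`, `t`, `x`, `y`.
#' @param windows data frame from [make_windows()].
#' @return Array `[window, animal, feature]` with dimnames.
#' @export
group_feature_windows <- function(positions, windows) {
  ids <- sort(unique(positions$animal_id))
  na <- length(ids)
  nw <- nrow(windows)
  wi <- assign_windows(positions$t, windows)
  keep <- !is.na(wi)
  ai <- match(positions$animal_id, ids)
  key <- (wi[keep] - 1L) * na + ai[keep]
  cnt <- tabulate(key, nbins = nw * na)
  sx <- rowsum(positions$x[keep], key)
  sy <- rowsum(positions$y[keep], key)
  mx <- matrix(NA_real_, na, nw)
  my <- matrix(NA_real_, na, nw)
  kk <- as.integer(rownames(sx))
  mx[kk] <- sx[, 1] / cnt[kk]
  my[kk] <- sy[, 1] / cnt[kk]
  out <- array(NA_real_, dim = c(nw, na, 11L),
               dimnames = list(windows$index, ids, group_feature_names()))
  for (w in seq_len(nw)) {
    present <- which(is.finite(mx[, w]))
    np <- length(present)
    if (np < 2L) next
    px <- mx[present, w]; py <- my[present, w]
    # share the focal-independent work (pairwise distances, snapshot PCA)
    D <- sqrt(outer(px, px, "-")^2 + outer(py, py, "-")^2)
    phi <- elongation_index(px, py)
    area <- group_area_proxy(px, py)
    for (k in seq_len(np)) {
      d <- D[k, -k]
      dx <- px[-k] - px[k]; dy <- py[-k] - py[k]
      mv <- dx != 0 | dy != 0
      dirs <- atan2(dy[mv], dx[mv])
      peri <- NA_real_
      if (np >= 3L && length(dirs) >= 2L) {
        ds <- sort(dirs)
        gaps <- c(diff(ds), ds[1] + 2 * pi - ds[length(ds)])
        peri <- (max(gaps) - 2 * pi / (np - 1)) / (2 * pi)
      }
      out[w, present[k], ] <- c(
        mean(d), stats::median(d), min(d),
        sum(d <= 2), sum(d <= 4), sum(d <= 8), sum(d <= 16),
        phi, area,
        if (length(dirs)) circular_rho(dirs) else NA_real_,
        peri
      )
    }
  }
  out
}
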