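#' Filter a normalised point cloud to vegetation returns
#'
#' Retains points classified as vegetation with a height strictly above 2 m
#' (the standard cut removing shrubs and low vegetation). Optionally drops
#' points whose absolute scan angle exceeds a cut-off; the cut used where
#' acquisition patterns demand it is 21 degrees.
#'
#' @param points Data frame with a `height` column (m, height above ground)
#'   and optionally `scan_angle` (degrees) and `intensity`.
#' @param height_cut Height threshold in m; points with `height > height_cut`
#'   are kept. Default 2.
#' @param angle_cut Optional absolute scan-angle cut in degrees; points with
#'   `abs(scan_angle) > angle_cut` are dropped. Default `NULL` (no filter).
#' @return The filtered data frame (possibly zero rows).
#' @export
filter_vegetation <- function(points, height_cut = 2, angle_cut = NULL) {
  stopifnot("height" %in% names(points))
  keep <- points$height > height_cut
  if (!is.null(angle_cut)) {
    stopifnot("scan_angle" %in% names(points))
    keep <- keep & abs(points$scan_angle) <= angle_cut
  }
  points[keep, , drop = FALSE]
}

#' Z-score normalisation of intensity values
#'
#' Normalises return intensities by dataset: subtract the mean and divide by
#' the standard deviation of a reference set (typically the points inside the
#' field plots of one acquisition). The sample standard deviation
#' (denominator n - 1) is used.
#'
#' @param values Intensities to normalise.
#' @param reference Reference intensities providing mean and sd. Defaults to
#'   `values`.
#' @return Normalised values.
#' @export
normalize_intensity <- function(values, reference = values) {
  if (length(reference) < 2) {
    stop("reference set must contain at least 2 values", call. = FALSE)
  }
  s <- stats::sd(reference)
  if (!is.finite(s) || s == 0) {
    stop("reference intensities have zero standard deviation", call. = FALSE)
  }
  (values - mean(reference)) / s
}

#' Generic point-cloud summary metrics
#'
#' Summary statistics of the filtered vegetation heights in one plot or cell:
#' mean, standard deviation, the deciles p10..p90 (linear interpolation
#' between order statistics, the type-7 convention) and canopy cover, the
#' fraction of all returns (before the vegetation filter) above 2 m.
#'
#' @param heights Vegetation heights after [filter_vegetation()].
#' @param n_total Total number of returns before filtering; used for the
#'   cover fraction. Defaults to `length(heights)` (cover 1 when anything
#'   remains).
#' @return Named numeric vector of metrics plus an `empty` flag (1 when no
#'   vegetation return was present, all other entries then 0).
#' @export
point_metrics <- function(heights, n_total = length(heights)) {
  pnames <- paste0("p", seq(10, 90, by = 10))
  if (length(heights) == 0) {
    out <- c(mean = 0, sd = 0, stats::setNames(numeric(9), pnames),
             cover = 0, empty = 1)
    return(out)
  }
  qs <- stats::quantile(heights, probs = seq(0.1, 0.9, by = 0.1),
                        names = FALSE, type = 7)
  c(mean = mean(heights),
    sd = if (length(heights) > 1) stats::sd(heights) else 0,
    stats::setNames(qs, pnames),
    cover = length(heights) / max(n_total, 1),
    empty = 0)
}

#' Local maxima of a canopy height model
#'
#' Detects treetop candidates as strict local maxima over the 8-neighbourhood
#' of a CHM raster; maxima with a height lower than 5 m are discarded.
#' Plateau cells (ties with a neighbour) are not maxima, which makes the
#' result deterministic.
#'
#' @param chm Numeric matrix of canopy heights (m); rows run north to south.
#' @param min_height Minimum height of a retained maximum (m), default 5.
#' @return Data frame with columns `row`, `col`, `height`, one row per
#'   retained maximum.
#' @export
local_maxima <- function(chm, min_height = 5) {
  stopifnot(is.matrix(chm), all(is.finite(chm)))
  nr <- nrow(chm); nc <- ncol(chm)
  pad <- matrix(-Inf, nr + 2, nc + 2)
  pad[2:(nr + 1), 2:(nc + 1)] <- chm
  is_max <- matrix(TRUE, nr, nc)
  for (dr in -1:1) {
    for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      nb <- pad[(2:(nr + 1)) + dr, (2:(nc + 1)) + dc, drop = FALSE]
      is_max <- is_max & (chm > nb)
    }
  }
  is_max <- is_max & (chm >= min_height)
  idx <- which(is_max, arr.ind = TRUE)
  data.frame(row = idx[, 1], col = idx[, 2], height = chm[idx])
}

#' ALS dominant height of a cell
#'
#' The mean height of the six highest CHM local maxima; when fewer than six
#' maxima are present, the mean of all of them. With no maxima at all the
#' dominant height is undefined and `NA` is returned.
#'
#' @param maxima_heights Heights (m) of the retained local maxima.
#' @return Dominant height in m, or `NA_real_` for an empty input.
#' @export
hdom_als <- function(maxima_heights) {
  if (length(maxima_heights) == 0) return(NA_real_)
  k <- min(6L, length(maxima_heights))
  mean(sort(maxima_heights, decreasing = TRUE)[seq_len(k)])
}
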