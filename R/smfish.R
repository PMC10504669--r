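#' Validate a spot-count-vs-threshold curve
#'
#' A threshold curve records, for an increasing sequence of detection
#' thresholds, the total number of spots found at each. Counts must be
#' non-increasing; at least 3 points are required.
#'
#' @param thresholds increasing numeric vector.
#' @param counts non-negative counts, same length.
#' @return a list with `thresholds` and `counts`.
#' @export
threshold_curve <- function(thresholds, counts) {
  if (length(thresholds) != length(counts))
    stop("thresholds and counts must have equal length")
  if (length(thresholds) < 3L) stop("need at least 3 curve points")
  if (is.unsorted(thresholds, strictly = TRUE))
    stop("thresholds must be strictly increasing")
  if (any(diff(counts) > 0)) stop("counts must be non-increasing")
  if (any(counts < 0)) stop("counts must be non-negative")
  list(thresholds = as.numeric(thresholds), counts = as.numeric(counts))
}

minmax <- function(v) {
  rng <- range(v)
  if (rng[1] == rng[2]) stop("axis is constant; cannot normalize")
  (v - rng[1]) / (rng[2] - rng[1])
}

#' Elbow point of a spot-count curve
#'
#' The detection threshold at the curve's knee: after min-max normalizing
#' both axes, the point with maximum perpendicular distance from the chord
#' joining the first and last curve points. Ties break toward the smallest
#' threshold, so a perfectly linear curve returns its first interior
#' point. The result is always an element of the input threshold sequence,
#' and is invariant to affine rescaling of either axis.
#'
#' @param curve a [threshold_curve()] (or a list with `thresholds`,
#'   `counts`).
#' @return the selected threshold value.
#' @export
elbow_threshold <- function(curve) {
  curve <- threshold_curve(curve$thresholds, curve$counts)
  tx <- minmax(curve$thresholds)
  ty <- minmax(curve$counts)
  n <- length(tx)
  # distance from chord (tx1,ty1)-(txn,tyn); endpoints have distance 0
  dx <- tx[n] - tx[1]; dy <- ty[n] - ty[1]
  d <- abs(dy * tx - dx * ty + tx[n] * ty[1] - ty[n] * tx[1]) /
    sqrt(dx^2 + dy^2)
  interior <- 2:(n - 1L)
  best <- interior[which.max(d[interior])]
  curve$thresholds[best]
}

# Composite Simpson integration on a possibly uneven grid (quadratic fit
# per interval pair; a trailing odd interval falls back to the trapezoid
# rule). Reduces to classic composite Simpson on even grids.
simpson_uneven <- function(x, y) {
  n <- length(x) - 1L  # intervals
  total <- 0
  i <- 1L
  while (i + 2L <= length(x)) {
    h1 <- x[i + 1L] - x[i]; h2 <- x[i + 2L] - x[i + 1L]
    total <- total + (h1 + h2) / 6 *
      ((2 - h2 / h1) * y[i] +
         (h1 + h2)^2 / (h1 * h2) * y[i + 1L] +
         (2 - h1 / h2) * y[i + 2L])
    i <- i + 2L
  }
  if (i + 1L == length(x)) {  # one interval left
    total <- total + (x[i + 1L] - x[i]) * (y[i] + y[i + 1L]) / 2
  }
  total
}

#' Normalized area under a spot-count curve
#'
#' Both axes are min-max normalized (subtract the minimum, divide by the
#' resulting maximum) and the area under the normalized counts is computed
#' with composite Simpson's rule. Values near 1 indicate a flat curve
#' (signal and noise intensities well separated only at extreme
#' thresholds, i.e. heavy mixing); low values indicate a sharp drop
#' separating signal from noise.
#'
#' @param curve a [threshold_curve()].
#' @return the area, in `[0, 1]` for monotone curves.
#' @export
normalized_auc <- function(curve) {
  curve <- threshold_curve(curve$thresholds, curve$counts)
  tx <- minmax(curve$thresholds)
  ty <- minmax(curve$counts)
  simpson_uneven(tx, ty)
}

#' Read a threshold curve from a CSV with columns threshold,count
#'
#' @param path CSV path.
#' @export
read_threshold_curve <- function(path) {
  df <- utils::read.csv(path)
  threshold_curve(df$threshold, df$count)
}
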