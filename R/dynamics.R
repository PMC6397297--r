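#' Track a cell centroid across a time-lapse sequence
#'
#' Segments each frame (robust threshold on the GFP channel, largest
#' connected component) and records the centroid in micrometres. The
#' centroid is intensity-weighted by default; `weight = "mask"` uses
#' the plain mask centroid. Frames with no foreground become gaps and
#' are linearly interpolated, up to `max_gap` consecutive missing
#' frames; longer gaps are an error.
#'
#' @param frames List of GFP intensity matrices, in time order.
#' @param pixel_size Micrometres per pixel.
#' @param dt Frame interval, minutes.
#' @param weight `"intensity"` or `"mask"`.
#' @param max_gap Maximum number of consecutive missing frames to
#'   interpolate.
#' @param k Threshold factor (MADs above median), as in
#'   [segment_cell()].
#' @return A `Track` data.frame with `t` (minutes), `x`, `y` (um).
#' @export
track_centroids <- function(frames, pixel_size = 1, dt = 10,
                            weight = c("intensity", "mask"), max_gap = 2,
                            k = 5) {
  weight <- match.arg(weight)
  stopifnot(length(frames) >= 1, pixel_size > 0, dt > 0)
  pos <- t(vapply(frames, function(fr) {
    mask <- largest_component(EBImage::fillHull(robust_foreground(fr, k)) > 0)
    if (!any(mask)) return(c(NA_real_, NA_real_))
    w <- which(mask, arr.ind = TRUE)
    wt <- if (weight == "intensity") fr[mask] else rep(1, nrow(w))
    c(sum(w[, 2] * wt), sum(w[, 1] * wt)) / sum(wt)
  }, numeric(2)))
  miss <- is.na(pos[, 1])
  if (any(miss)) {
    runs <- rle(miss)
    bad <- runs$lengths[runs$values]
    if (miss[1] || miss[length(miss)] || any(bad > max_gap))
      stop(sprintf("unrecoverable tracking gap (%d consecutive empty frames)",
                   max(bad)), call. = FALSE)
    for (jcol in 1:2)
      pos[, jcol] <- stats::approx(which(!miss), pos[!miss, jcol],
                                   xout = seq_len(nrow(pos)))$y
  }
  structure(data.frame(t = (seq_len(nrow(pos)) - 1) * dt,
                       x = pos[, 1] * pixel_size, y = pos[, 2] * pixel_size),
            class = c("Track", "data.frame"))
}

#' Total distance migrated
#'
#' Sum of Euclidean step lengths along a centroid track.
#'
#' @param track data.frame with `x`, `y` positions (um) in time order.
#' @return Distance in um.
#' @examples
#' total_distance(data.frame(x = c(0, 3), y = c(0, 4)))  # 5
#' @export
total_distance <- function(track) {
  stopifnot(is.data.frame(track), nrow(track) >= 2)
  sum(sqrt(diff(track$x)^2 + diff(track$y)^2))
}

#' Migration directionality
#'
#' Net displacement (Euclidean distance between first and last centroid
#' positions) divided by the total distance travelled; 1 for a
#' perfectly straight path, 0 for a closed loop. Undefined (NA) when
#' the cell did not move.
#'
#' @param track data.frame with `x`, `y` positions (um) in time order.
#' @return Value in [0, 1], or `NA_real_` for a zero-length path.
#' @export
directionality <- function(track) {
  stopifnot(is.data.frame(track), nrow(track) >= 2)
  total <- total_distance(track)
  if (total == 0) return(NA_real_)
  net <- sqrt((track$x[nrow(track)] - track$x[1])^2 +
                (track$y[nrow(track)] - track$y[1])^2)
  net / total
}

#' F-actin interframe change
#'
#' Signed percent change of F-actin amount between successive frames:
#' `IFC_i = 100 * (FA_{i+1} - FA_i) / FA_i`.
#'
#' @param fa An `FASeries` data.frame (columns `t`, `fa`) or a numeric
#'   vector of F-actin amounts.
#' @return Numeric vector of length `n - 1`, signed percent.
#' @export
interframe_change <- function(fa) {
  v <- if (is.data.frame(fa)) fa$fa else fa
  stopifnot(is.numeric(v), length(v) >= 2)
  if (any(v[-length(v)] <= 0))
    stop("F-actin amounts must be positive", call. = FALSE)
  100 * diff(v) / v[-length(v)]
}

#' F-actin disassembly after drug treatment
#'
#' Percent drop in F-actin amount over the treatment window:
#' `100 * (FA(0) - FA(t_end)) / FA(0)`. Negative values indicate net
#' assembly.
#'
#' @param fa An `FASeries` data.frame with columns `t` (minutes) and
#'   `fa`.
#' @param t_end Endpoint time in minutes (default 30, the standard
#'   latrunculin window).
#' @return Percent disassembly (scalar).
#' @export
disassembly <- function(fa, t_end = 30) {
  stopifnot(is.data.frame(fa), all(c("t", "fa") %in% names(fa)))
  i0 <- which(fa$t == 0)
  i1 <- which(fa$t == t_end)
  if (length(i0) != 1 || length(i1) != 1)
    stop(sprintf("series must contain frames at t = 0 and t = %g min", t_end),
         call. = FALSE)
  if (fa$fa[i0] <= 0) stop("FA(0) must be positive", call. = FALSE)
  100 * (fa$fa[i0] - fa$fa[i1]) / fa$fa[i0]
}
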