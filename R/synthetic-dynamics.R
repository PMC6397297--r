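#' Migration track generator configuration
#'
#' Persistent-random-walk centroid tracks sampled on a fixed time grid,
#' emulating long-term single-cell tracking (default: 18 h at 10-min
#' intervals). Speed and directional persistence may depend on
#' expression through user-supplied laws.
#'
#' @param n_steps Number of steps (>= 2 positions are produced for
#'   `n_steps >= 1`; a track has `n_steps + 1` positions).
#' @param dt Frame interval, minutes.
#' @param speed_law `function(expression)` returning speed in um/min.
#' @param persistence_law `function(expression)` returning the
#'   directional persistence in [0, 1]: the expected per-step resultant
#'   of the turning-angle distribution (1 = straight, 0 = uncorrelated).
#' @param seed Integer seed.
#' @return A `track_config` list.
#' @export
track_config <- function(n_steps = 108, dt = 10,
                         speed_law = function(e) rep(0.5, length(e)),
                         persistence_law = function(e) rep(0.6, length(e)),
                         seed = 1) {
  stopifnot(n_steps >= 1, dt > 0, is.function(speed_law),
            is.function(persistence_law))
  structure(list(n_steps = as.integer(n_steps), dt = dt,
                 speed_law = speed_law, persistence_law = persistence_law,
                 seed = as.integer(seed)),
            class = "track_config")
}

#' Generate persistent-random-walk tracks
#'
#' One track per expression value. The heading turns by a wrapped-normal
#' increment whose mean resultant length equals the configured
#' persistence (`sd = sqrt(-2 log p)`; `p = 0` draws uniform turns,
#' `p = 1` walks straight). Step length is `speed * dt`.
#'
#' @param tc A [track_config()].
#' @param expressions Positive expression levels, one per track.
#' @return List of tracks; each is a data.frame with `t` (minutes),
#'   `x`, `y` (um), of `n_steps + 1` rows, carrying attributes `speed`
#'   and `persistence`.
#' @export
generate_tracks <- function(tc, expressions) {
  stopifnot(inherits(tc, "track_config"), all(expressions > 0))
  set.seed(tc$seed)
  lapply(seq_along(expressions), function(i) {
    e <- expressions[i]
    sp <- tc$speed_law(e)
    p <- tc$persistence_law(e)
    stopifnot(p >= 0, p <= 1, sp >= 0)
    n <- tc$n_steps
    turns <- if (p >= 1) rep(0, n)
             else if (p <= 0) stats::runif(n, -pi, pi)
             else stats::rnorm(n, 0, sqrt(-2 * log(p)))
    heading <- stats::runif(1, 0, 2 * pi) + cumsum(c(0, turns[-n]))
    step <- sp * tc$dt
    x <- c(0, cumsum(step * cos(heading)))
    y <- c(0, cumsum(step * sin(heading)))
    out <- data.frame(t = seq(0, by = tc$dt, length.out = n + 1), x = x, y = y)
    attr(out, "speed") <- sp
    attr(out, "persistence") <- p
    attr(out, "expression") <- e
    class(out) <- c("Track", "data.frame")
    out
  })
}

#' Exponential F-actin decay series under drug treatment
#'
#' `FA(t) = fa0 * exp(-rate * t)` on a fixed grid (default 0-30 min at
#' 2-min intervals, the standard latrunculin imaging protocol), with
#' optional multiplicative lognormal measurement noise.
#'
#' @param fa0 Initial F-actin amount, counts (> 0).
#' @param rate Decay rate, per minute (>= 0).
#' @param t_end End time, minutes.
#' @param dt Sampling interval, minutes.
#' @param noise_cv CV of multiplicative lognormal noise (0 = none).
#' @param seed Optional seed (only used when `noise_cv > 0`).
#' @return An `FASeries` data.frame with columns `t` (minutes) and `fa`.
#' @export
generate_decay_series <- function(fa0, rate, t_end = 30, dt = 2,
                                  noise_cv = 0, seed = NULL) {
  stopifnot(fa0 > 0, rate >= 0, dt > 0, t_end >= 0, noise_cv >= 0)
  t <- seq(0, t_end, by = dt)
  fa <- fa0 * exp(-rate * t)
  if (noise_cv > 0) {
    if (!is.null(seed)) set.seed(seed)
    fa <- fa * exp(stats::rnorm(length(fa), 0, sqrt(log(1 + noise_cv^2))))
  }
  structure(data.frame(t = t, fa = fa), class = c("FASeries", "data.frame"))
}
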