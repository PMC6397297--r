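#' Build a dose-response curve from per-cell records
#'
#' Sorts cells by total GFP expression and cuts them into consecutive
#' equal-count bins (sizes differ by at most one, each >= `n_min`).
#' Each bin is summarized by its representative expression (geometric
#' mean of member total GFP) and a pooled descriptor statistic with
#' matching dispersion: geometric mean with geometric SD, arithmetic
#' mean with SD, or median with quartiles — the per-descriptor pooling
#' choices used when reporting these curves.
#'
#' @param records data.frame with a `total_gfp` column and the
#'   descriptor column.
#' @param descriptor Name of the descriptor column.
#' @param n_min Minimum cells per bin (default 100; smaller values
#'   match sparser experiments).
#' @param pooling One of `"gmean"`, `"mean"`, `"median"`.
#' @return A `DoseResponseCurve` data.frame: `expression`, `value`,
#'   `lo`, `hi` (dispersion band), `n`; attributes `descriptor`,
#'   `pooling`.
#' @export
build_drc <- function(records, descriptor, n_min = 100,
                      pooling = c("gmean", "mean", "median")) {
  pooling <- match.arg(pooling)
  stopifnot(is.data.frame(records), "total_gfp" %in% names(records),
            descriptor %in% names(records), n_min >= 2)
  d <- records[[descriptor]]
  e <- records$total_gfp
  ok <- is.finite(d) & is.finite(e) & e > 0
  if (pooling == "gmean") ok <- ok & d > 0
  d <- d[ok]; e <- e[ok]
  n <- length(d)
  if (n < 2 * n_min)
    stop(sprintf(
      "too few records: %d usable, need at least %d (2 * n_min)", n,
      2 * n_min), call. = FALSE)
  ord <- order(e)
  d <- d[ord]; e <- e[ord]
  n_bins <- n %/% n_min
  sizes <- rep(n %/% n_bins, n_bins)
  extra <- n %% n_bins
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  idx <- rep(seq_len(n_bins), sizes)
  pool <- function(x) switch(pooling,
    gmean = c(gmean(x), gmean(x) / gsd(x), gmean(x) * gsd(x)),
    mean = c(mean(x), mean(x) - stats::sd(x), mean(x) + stats::sd(x)),
    median = unname(stats::quantile(x, c(0.5, 0.25, 0.75))))
  stats_m <- vapply(split(d, idx), pool, numeric(3))
  out <- data.frame(
    expression = vapply(split(e, idx), gmean, numeric(1)),
    value = stats_m[1, ], lo = stats_m[2, ], hi = stats_m[3, ],
    n = sizes)
  rownames(out) <- NULL
  structure(out, descriptor = descriptor, pooling = pooling,
            class = c("DoseResponseCurve", "data.frame"))
}

#' Ratio-of-variances series along a curve
#'
#' For each interior index `i` of the ordered bin statistics `d`,
#' computes the ratio of the sample variances (denominator `n - 1`) in
#' the two N-sized windows flanking the point:
#' `RoV_i = var(d[i+1 .. i+N]) / var(d[i-N .. i-1])`.
#' Peaks mark entries into regions of raised variability — transitions
#' between dose-response regimes. For positive-valued descriptors the
#' statistic is computed on `log(d)` (`log = TRUE`, the default), which
#' makes it invariant to rescaling the descriptor. Indices whose
#' trailing-window variance is zero are returned as `NA` (flagged
#' undefined, never `Inf`).
#'
#' @param d Numeric vector of ordered bin statistics (length >= 2N+1),
#'   or a `DoseResponseCurve` (its `value` column is used).
#' @param N Window size (>= 2). Default 6.
#' @param log Compute on the log scale? Requires positive `d`.
#' @return An `RoVSeries` data.frame with `index` (position in `d`) and
#'   `rov`; attribute `N`.
#' @examples
#' rov_series(c(1, 2, 3, 10, 20, 30), N = 2, log = FALSE)$rov[1]  # 100
#' @export
rov_series <- function(d, N = 6, log = TRUE) {
  curve <- NULL
  if (inherits(d, "DoseResponseCurve")) {
    curve <- d
    d <- d$value
  }
  stopifnot(is.numeric(d), N >= 2)
  n <- length(d)
  if (n < 2 * N + 1)
    stop(sprintf("series too short: length %d < 2N+1 = %d", n, 2 * N + 1),
         call. = FALSE)
  if (log) {
    if (any(d <= 0))
      stop("log-scale RoV requires positive values", call. = FALSE)
    d <- base::log(d)
  }
  idx <- (N + 1):(n - N)
  rov <- vapply(idx, function(i) {
    lead <- stats::var(d[(i + 1):(i + N)])
    trail <- stats::var(d[(i - N):(i - 1)])
    if (trail == 0) NA_real_ else lead / trail
  }, numeric(1))
  structure(data.frame(index = idx, rov = rov),
            N = N, log = log, curve = curve,
            class = c("RoVSeries", "data.frame"))
}

#' Detect regime-transition candidates from an RoV series
#'
#' Local extrema of `log(RoV)` whose magnitude exceeds a prominence
#' threshold are transition candidates: a positive extremum (variance
#' rising ahead of the point) marks the onset of the dose-response
#' regime, a negative one (variance settling) marks entry into the
#' saturation plateau. The two largest-magnitude extrema, ordered by
#' expression, become the curve's lower/upper candidate thresholds; 0,
#' 1 or 2 candidates may be returned. Each candidate's reported
#' position is the boundary of its contiguous super-threshold run
#' (trailing edge for an onset, leading edge for a saturation), which
#' tracks the breakpoint more tightly than the extremum itself.
#'
#' The default prominence (`prominence = "fdist"`) is calibrated from
#' the null distribution of the statistic: under a flat regime the RoV
#' of N-sized windows is F(N-1, N-1)-distributed, so the threshold is
#' the two-sided F quantile at familywise level `alpha` across the
#' series. A fixed threshold on `|log RoV|` can be supplied instead as
#' a number (e.g. `log(4)`).
#'
#' @param rov An `RoVSeries` from [rov_series()].
#' @param curve The `DoseResponseCurve` the series was computed from
#'   (optional if the series carries it); supplies expression values.
#' @param prominence `"fdist"` or a positive number (threshold on
#'   `|log RoV|`).
#' @param alpha Per-comparison level for `"fdist"` after the overlap correction; a flat curve then yields a spurious candidate in roughly 2 * alpha of runs.
#' @return data.frame with 0-2 rows: `index`, `expression`,
#'   `log_rov`, `type` (`"lower"`/`"upper"`).
#' @export
detect_thresholds <- function(rov, curve = NULL, prominence = "fdist",
                              alpha = 0.01) {
  stopifnot(inherits(rov, "RoVSeries"))
  if (is.null(curve)) curve <- attr(rov, "curve")
  N <- attr(rov, "N")
  lr <- base::log(rov$rov)
  m <- sum(is.finite(lr))
  if (identical(prominence, "fdist")) {
    # adjacent RoV values share most of their windows, so the series
    # carries about m / N independent comparisons, not m
    m_eff <- max(1, ceiling(m / N))
    thr <- base::log(stats::qf(1 - alpha / (2 * m_eff), N - 1, N - 1))
  } else {
    stopifnot(is.numeric(prominence), prominence > 0)
    thr <- prominence
  }
  cand <- integer(0)
  for (i in seq_along(lr)) {
    if (!is.finite(lr[i]) || abs(lr[i]) <= thr) next
    lo <- max(1, i - 1); hi <- min(length(lr), i + 1)
    nb <- lr[setdiff(lo:hi, i)]
    nb <- nb[is.finite(nb)]
    if (all(abs(lr[i]) >= abs(nb))) cand <- c(cand, i)
  }
  # the RoV stays elevated over ~N points around one transition, which
  # can split into several local maxima: keep extrema at least N apart,
  # strongest first, then the two most prominent overall
  if (length(cand) > 1) {
    ord <- cand[order(abs(lr[cand]), decreasing = TRUE)]
    sel <- integer(0)
    for (i in ord) if (!length(sel) || min(abs(sel - i)) > N) sel <- c(sel, i)
    cand <- sel
  }
  if (length(cand) > 2)
    cand <- cand[order(abs(lr[cand]), decreasing = TRUE)][1:2]
  cand <- sort(cand)
  # the transition sits at the boundary of the contiguous
  # super-threshold run, not at its extremum: for an onset the run
  # ends one point past the breakpoint (once the trailing window has
  # absorbed the new variability), for a saturation it starts one
  # point before it
  pos <- vapply(cand, function(i) {
    s <- sign(lr[i])
    run <- i
    j <- i
    while (j > 1 && is.finite(lr[j - 1]) && s * lr[j - 1] > thr) {
      j <- j - 1; run <- c(j, run)
    }
    j <- i
    while (j < length(lr) && is.finite(lr[j + 1]) && s * lr[j + 1] > thr) {
      j <- j + 1; run <- c(run, j)
    }
    if (s > 0) max(min(max(run) - 1L, max(run)), min(run))
    else min(max(min(run) + 1L, min(run)), max(run))
  }, numeric(1))
  out <- data.frame(index = rov$index[pos],
                    log_rov = lr[cand],
                    type = ifelse(lr[cand] > 0, "lower", "upper"),
                    stringsAsFactors = FALSE)
  out$expression <- if (!is.null(curve)) curve$expression[out$index]
                    else NA_real_
  out[, c("index", "expression", "log_rov", "type")]
}

#' Pool per-curve candidates into global thresholds
#'
#' Averages (geometric mean, since expression spans decades) all lower
#' candidates into the global no-effect/dose-response threshold `G1`,
#' and all upper candidates into the dose-response/saturation
#' threshold `G2`.
#'
#' @param candidates data.frame (or list of data.frames, one per
#'   descriptor curve) with columns `expression` and `type` as
#'   returned by [detect_thresholds()].
#' @return Named numeric vector `c(G1 = ..., G2 = ...)`.
#' @export
global_thresholds <- function(candidates) {
  if (is.data.frame(candidates)) candidates <- list(candidates)
  all_c <- do.call(rbind, candidates)
  lower <- all_c$expression[all_c$type == "lower"]
  upper <- all_c$expression[all_c$type == "upper"]
  lower <- lower[is.finite(lower)]
  upper <- upper[is.finite(upper)]
  if (length(lower) == 0 || length(upper) == 0)
    stop("need at least one lower and one upper candidate", call. = FALSE)
  g1 <- gmean(lower); g2 <- gmean(upper)
  if (g1 >= g2)
    stop(sprintf("crossed thresholds: G1 = %.4g >= G2 = %.4g", g1, g2),
         call. = FALSE)
  c(G1 = g1, G2 = g2)
}

#' Sort cells into expression regimes
#'
#' Labels each cell by thresholding its total GFP at the global
#' thresholds, using half-open intervals: `[0, G1)` no-effect,
#' `[G1, G2)` dose-response, `[G2, Inf)` saturation.
#'
#' @param records data.frame with a `total_gfp` column.
#' @param g1,g2 Global thresholds, `g1 < g2`.
#' @return `records` with a `regime` factor column added; regime counts
#'   are attached as attribute `counts`.
#' @export
assign_regimes <- function(records, g1, g2) {
  stopifnot(is.data.frame(records), "total_gfp" %in% names(records),
            g1 < g2)
  lev <- c("no_effect", "dose_response", "saturation")
  records$regime <- factor(regime_label(records$total_gfp, g1, g2),
                           levels = lev)
  attr(records, "counts") <- table(records$regime)
  records
}
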