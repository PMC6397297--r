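#' Noise model for synthetic micrographs
#'
#' Standard epifluorescence noise: a planar background (level plus a
#' fractional linear tilt across the field), Poisson shot noise on the
#' total signal, and additive Gaussian read noise.
#'
#' @param background_level Mean background, counts.
#' @param background_gradient Fractional tilt of the background plane
#'   across the field (0 = flat).
#' @param gaussian_sd Read-noise standard deviation, counts.
#' @param use_poisson Apply Poisson shot noise to signal + background?
#' @return A `noise_config` list.
#' @export
noise_config <- function(background_level = 100, background_gradient = 0.05,
                         gaussian_sd = 5, use_poisson = TRUE) {
  stopifnot(background_level >= 0, background_gradient >= 0, gaussian_sd >= 0)
  structure(list(background_level = background_level,
                 background_gradient = background_gradient,
                 gaussian_sd = gaussian_sd,
                 use_poisson = isTRUE(use_poisson)),
            class = "noise_config")
}

#' @rdname noise_config
#' @export
zero_noise <- function() noise_config(0, 0, 0, FALSE)

#' Default per-parameter transfer functions
#'
#' One [transfer_function()] per simulated morphometric parameter, all
#' sharing the population breakpoints. Fold changes mirror the
#' magnitudes this class of experiment reports: a 10-fold spread-area
#' increase, a 50-fold increase in fibre-organized stain (F-actin
#' amount), thicker fibres, higher orientation coherence, mildly larger
#' nuclei, and decreasing aspect ratio and stellate protrusion
#' amplitude.
#'
#' @param t1,t2 Shared expression breakpoints.
#' @param noise_cv Common cell-to-cell scatter CV.
#' @return Named list of `transfer_function` objects.
#' @export
default_transfer_set <- function(t1, t2, noise_cv = 0.15) {
  list(
    area            = transfer_function(500, 5000, t1, t2, noise_cv),
    aspect_ratio    = transfer_function(3.0, 1.5, t1, t2, noise_cv / 2),
    stellate        = transfer_function(0.30, 0.08, t1, t2, noise_cv),
    fibre_amount    = transfer_function(2e4, 1e6, t1, t2, noise_cv),
    fibre_thickness = transfer_function(1.3, 3.3, t1, t2, noise_cv / 2),
    orientation_kappa = transfer_function(1.5, 8, t1, t2, noise_cv / 2),
    n_fibres        = transfer_function(7, 14, t1, t2, noise_cv),
    nucleus_area    = transfer_function(160, 240, t1, t2, noise_cv / 2)
  )
}

#' Synthetic cell population configuration
#'
#' Describes a population of single-cell fields of view: a lognormal
#' cell-to-cell expression law spanning several decades (emulating the
#' broad vector-copy-number variation of viral transduction), piecewise
#' flat/log-linear/flat transfer functions mapping expression to each
#' morphometric parameter, and the rendering geometry. Cells are
#' star-convex polygons (cosine protrusions of controllable amplitude
#' drive the stellate factor; elliptical stretch drives aspect ratio)
#' with elliptical nuclei and constant-width anti-aliased fibre
#' capsules whose orientations follow an axial von Mises law.
#'
#' @param n_cells Number of cells (>= 1), one field of view each.
#' @param gfp_log_mean,gfp_log_sd Mean and sd of log10 expression.
#' @param transfer Named list of [transfer_function()]s; defaults to
#'   [default_transfer_set()] with breakpoints `t1_decades` and
#'   `t2_decades` above the median expression.
#' @param t1_decades,t2_decades Breakpoint offsets (decades above the
#'   median expression) used when `transfer` is not supplied.
#' @param image_size Field-of-view size in px, length-2 (>= 64 each).
#' @param pixel_size Pixel size, micrometres per px.
#' @param noise A [noise_config()].
#' @param stain_diffuse Diffuse (non-fibre) cytoplasmic stain level,
#'   counts per pixel.
#' @param dapi_level Nuclear DAPI intensity, counts per pixel.
#' @param n_lobes Number of cosine protrusion lobes on the cell outline.
#' @param seed Integer seed; every generator draw flows from it.
#' @return A `population_config` list with `t1`, `t2` resolved.
#' @seealso [generate_population()], [simulate_cell()]
#' @export
population_config <- function(n_cells = 200, gfp_log_mean = 5,
                              gfp_log_sd = 1.2, transfer = NULL,
                              t1_decades = 1, t2_decades = 2,
                              image_size = c(256, 256), pixel_size = 0.65,
                              noise = noise_config(), stain_diffuse = 80,
                              dapi_level = 150, n_lobes = 5, seed = 1) {
  stopifnot(n_cells >= 1, gfp_log_sd >= 0, length(image_size) == 2,
            all(image_size >= 64), pixel_size > 0,
            inherits(noise, "noise_config"), stain_diffuse >= 0,
            t1_decades < t2_decades)
  if (is.null(transfer)) {
    med <- 10^gfp_log_mean
    transfer <- default_transfer_set(med * 10^t1_decades, med * 10^t2_decades)
  }
  stopifnot(all(vapply(transfer, inherits, TRUE, "transfer_function")))
  t1 <- transfer[[1]]$t1
  t2 <- transfer[[1]]$t2
  structure(list(n_cells = as.integer(n_cells), gfp_log_mean = gfp_log_mean,
                 gfp_log_sd = gfp_log_sd, transfer = transfer,
                 t1 = t1, t2 = t2,
                 image_size = as.integer(image_size),
                 pixel_size = pixel_size, noise = noise,
                 stain_diffuse = stain_diffuse, dapi_level = dapi_level,
                 n_lobes = as.integer(n_lobes), seed = as.integer(seed)),
            class = "population_config")
}

#' Multi-channel single-cell image set
#'
#' One registered field of view: GFP (probe expression), stain
#' (phalloidin/antibody, TRITC) and DAPI channels of equal shape, with
#' pixel-size metadata. Synthetic sets carry a `truth` list (masks,
#' noiseless fibre signal, generating parameters).
#'
#' @param gfp,stain,dapi Non-negative intensity matrices, equal shape.
#' @param pixel_size Micrometres per pixel (> 0).
#' @param id Identifier string.
#' @param truth Optional ground-truth list (synthetic data only).
#' @return A `CellImageSet`.
#' @export
cell_image_set <- function(gfp, stain, dapi, pixel_size, id = "cell",
                           truth = NULL) {
  stopifnot(is.matrix(gfp), is.matrix(stain), is.matrix(dapi))
  if (!all(dim(gfp) == dim(stain)) || !all(dim(gfp) == dim(dapi)))
    stop(sprintf("channel shapes differ: gfp %s, stain %s, dapi %s",
                 paste(dim(gfp), collapse = "x"),
                 paste(dim(stain), collapse = "x"),
                 paste(dim(dapi), collapse = "x")), call. = FALSE)
  stopifnot(min(gfp) >= 0, min(stain) >= 0, min(dapi) >= 0, pixel_size > 0)
  structure(list(gfp = gfp, stain = stain, dapi = dapi,
                 pixel_size = pixel_size, id = id, truth = truth),
            class = "CellImageSet")
}

#' @export
print.CellImageSet <- function(x, ...) {
  cat(sprintf("CellImageSet '%s': %d x %d px, %.3g um/px%s\n", x$id,
              nrow(x$gfp), ncol(x$gfp), x$pixel_size,
              if (!is.null(x$truth)) " (with ground truth)" else ""))
  invisible(x)
}

# ---- fibre capsule rendering ------------------------------------------------

# Cross-section: flat core of full width (w - 1) px with a 1-px linear
# anti-aliasing ramp on each side; total support width w + 1, integral
# of the profile exactly w (for w >= 1).
capsule_profile <- function(d, w) clamp(w / 2 + 0.5 - d, 0, 1)

# Closed-ish form of the 2-D integral of one capsule: straight part
# w * L plus the two end caps (radial profile integrated numerically).
capsule_integral <- function(length, w) {
  h <- w / 2
  cap <- stats::integrate(function(r) capsule_profile(r, w) * 2 * pi * r,
                          0, h + 0.5)$value
  w * length + cap
}

#' Render one anti-aliased fibre capsule
#'
#' Adds a constant-width segment with a 1-px anti-aliased edge to an
#' image. Exposed as the rendering primitive used by the population
#' generator so that segmentation accuracy can be tested against exact
#' geometric ground truth.
#'
#' @param img Intensity matrix to add to.
#' @param x0,y0,x1,y1 Segment endpoints (x = column, y = row, px).
#' @param width Fibre width in px (>= 1; the profile integrates to
#'   `width` per unit length).
#' @param amplitude Peak intensity, counts.
#' @return The image with the capsule added.
#' @export
render_capsule <- function(img, x0, y0, x1, y1, width, amplitude) {
  h <- width / 2
  pad <- ceiling(h + 1.5)
  rs <- max(1L, floor(min(y0, y1)) - pad):min(nrow(img), ceiling(max(y0, y1)) + pad)
  cs <- max(1L, floor(min(x0, x1)) - pad):min(ncol(img), ceiling(max(x0, x1)) + pad)
  px <- matrix(rep(cs, each = length(rs)), length(rs))
  py <- matrix(rep(rs, length(cs)), length(rs))
  vx <- x1 - x0; vy <- y1 - y0
  len2 <- vx^2 + vy^2
  tt <- if (len2 == 0) 0 else clamp(((px - x0) * vx + (py - y0) * vy) / len2, 0, 1)
  d <- sqrt((px - (x0 + tt * vx))^2 + (py - (y0 + tt * vy))^2)
  img[rs, cs] <- img[rs, cs] + amplitude * capsule_profile(d, width)
  img
}

# ---- star-convex cell geometry ----------------------------------------------

# Radius of the star-convex outline at polar angle theta (unstretched).
star_radius <- function(theta, r0, amp, k, phase) {
  r0 * (1 + amp * cos(k * theta + phase))
}

# Rasterize the stretched star-convex cell; returns mask + geometry.
rasterize_cell <- function(dim, cx, cy, r0, amp, k, phase, ax, ay) {
  g <- coord_grid(dim)
  u <- (g$x - cx) / ax
  v <- (g$y - cy) / ay
  r <- sqrt(u^2 + v^2)
  th <- atan2(v, u)
  mask <- r <= star_radius(th, r0, amp, k, phase)
  mask
}

# Is (x, y) inside the scaled-down (factor f) cell outline?
inside_cell <- function(x, y, geo, f = 1) {
  u <- (x - geo$cx) / geo$ax
  v <- (y - geo$cy) / geo$ay
  sqrt(u^2 + v^2) <= f * star_radius(atan2(v, u), geo$r0, geo$amp,
                                     geo$k, geo$phase)
}

# Rasterize an ellipse mask.
rasterize_ellipse <- function(dim, cx, cy, a, b, theta) {
  g <- coord_grid(dim)
  dx <- g$x - cx; dy <- g$y - cy
  u <- dx * cos(theta) + dy * sin(theta)
  v <- -dx * sin(theta) + dy * cos(theta)
  (u / a)^2 + (v / b)^2 <= 1
}

apply_noise <- function(img, noise, rng_ok = TRUE) {
  n <- noise
  dimi <- dim(img)
  g <- coord_grid(dimi)
  plane <- n$background_level *
    (1 + n$background_gradient * ((g$x / dimi[2] - 0.5) +
                                    (g$y / dimi[1] - 0.5)) / 2)
  out <- img + plane
  if (n$use_poisson) out <- matrix(stats::rpois(length(out), clamp(out, 0, Inf)),
                                   dimi[1], dimi[2])
  if (n$gaussian_sd > 0) out <- out + stats::rnorm(length(out), 0, n$gaussian_sd)
  clamp(out, 0, Inf)
}

# ---- single-cell renderer ---------------------------------------------------

#' Render one synthetic cell with full ground truth
#'
#' Draws morphometric parameters for a given expression level from the
#' configured transfer functions (unless supplied explicitly), renders
#' the three channels, and returns the image set with its ground truth.
#' The GFP channel integrates, before noise, to exactly the expression
#' value (proportionality constant 1 count per expression unit).
#'
#' @param config A [population_config()].
#' @param expression Positive expression level (counts).
#' @param params Optional named list overriding drawn parameters:
#'   `area_um2`, `aspect_ratio`, `stellate`, `n_fibres`,
#'   `fibre_thickness_um`, `orientation_kappa`, `nucleus_area_um2`,
#'   `fibre_amount`.
#' @param id Identifier.
#' @return A [cell_image_set()] whose `truth` holds `cell_mask`,
#'   `nucleus_mask`, `fibre_signal` (noiseless raster), `fibres`
#'   (per-fibre geometry), and the generating parameter values.
#' @export
simulate_cell <- function(config, expression, params = NULL, id = "cell") {
  stopifnot(inherits(config, "population_config"), expression > 0)
  tfs <- config$transfer
  ps <- config$pixel_size
  dimi <- config$image_size
  draw <- function(name, default) {
    if (!is.null(params[[name]])) return(params[[name]])
    if (!is.null(tfs[[name]])) return(sample_parameter(tfs[[name]], expression))
    default
  }
  margin <- 6
  for (attempt in 1:10) {
    area_um2 <- draw("area_um2", 1000)
    if (is.null(params[["area_um2"]]) && !is.null(tfs[["area"]]))
      area_um2 <- sample_parameter(tfs[["area"]], expression)
    q <- max(1, draw("aspect_ratio", 2))
    amp <- clamp(draw("stellate", 0.2), 0, 0.45)
    area_px <- area_um2 / ps^2
    r0 <- sqrt(area_px / (pi * (1 + amp^2 / 2)))
    ax <- sqrt(q); ay <- 1 / sqrt(q)
    rmax <- max(ax, ay) * r0 * (1 + amp)
    jit <- stats::runif(2, -4, 4)
    if (rmax + margin + 4 <= min(dimi) / 2) break
    if (attempt == 10)
      stop("cell geometry exceeds image bounds after 10 redraws", call. = FALSE)
  }
  cx <- (dimi[2] + 1) / 2 + jit[1]
  cy <- (dimi[1] + 1) / 2 + jit[2]
  phase <- stats::runif(1, 0, 2 * pi)
  geo <- list(cx = cx, cy = cy, r0 = r0, amp = amp, k = config$n_lobes,
              phase = phase, ax = ax, ay = ay)
  cell_mask <- rasterize_cell(dimi, cx, cy, r0, amp, config$n_lobes, phase,
                              ax, ay)
  n_px <- sum(cell_mask)

  # nucleus: centred ellipse, area capped at 30% of the cell
  nuc_um2 <- draw("nucleus_area_um2", 180)
  if (is.null(params[["nucleus_area_um2"]]) && !is.null(tfs[["nucleus_area"]]))
    nuc_um2 <- sample_parameter(tfs[["nucleus_area"]], expression)
  nuc_px <- min(nuc_um2 / ps^2, 0.3 * n_px)
  nratio <- 1.3
  nb <- sqrt(nuc_px / (pi * nratio))
  na_ <- nratio * nb
  ntheta <- stats::runif(1, 0, pi)
  nucleus_mask <- rasterize_ellipse(dimi, cx, cy, na_, nb, ntheta) & cell_mask

  # fibres
  n_f <- max(1L, round(draw("n_fibres", 8)))
  if (is.null(params[["n_fibres"]]) && !is.null(tfs[["n_fibres"]]))
    n_f <- max(1L, round(sample_parameter(tfs[["n_fibres"]], expression)))
  w_um <- draw("fibre_thickness_um", 2.6)
  if (is.null(params[["fibre_thickness_um"]]) && !is.null(tfs[["fibre_thickness"]]))
    w_um <- sample_parameter(tfs[["fibre_thickness"]], expression)
  w_px <- clamp(w_um / ps, 1.5, 9)
  kappa <- draw("orientation_kappa", 4)
  fa_target <- draw("fibre_amount", 1e5)
  mu <- stats::runif(1, 0, pi)
  angles <- (rvonmises(n_f, 2 * mu, kappa) / 2) %% pi
  fibres <- vector("list", n_f)
  for (j in seq_len(n_f)) {
    for (try_f in 1:8) {
      ang <- angles[j]
      rr <- 0.5 * r0 * sqrt(stats::runif(1))
      pang <- stats::runif(1, 0, 2 * pi)
      ax0 <- cx + ax * rr * cos(pang)
      ay0 <- cy + ay * rr * sin(pang)
      dxy <- c(cos(ang), sin(ang))
      tmax <- 2 * rmax
      tgrid <- seq(0, tmax, by = 1)
      fwd <- tgrid[inside_cell(ax0 + tgrid * dxy[1], ay0 + tgrid * dxy[2],
                               geo, 0.85)]
      bwd <- tgrid[inside_cell(ax0 - tgrid * dxy[1], ay0 - tgrid * dxy[2],
                               geo, 0.85)]
      tf_ <- if (length(fwd)) max(fwd) else 0
      tb_ <- if (length(bwd)) max(bwd) else 0
      if (tf_ + tb_ >= 12 || try_f == 8) {
        fibres[[j]] <- data.frame(
          x0 = ax0 - tb_ * dxy[1], y0 = ay0 - tb_ * dxy[2],
          x1 = ax0 + tf_ * dxy[1], y1 = ay0 + tf_ * dxy[2],
          angle = ang, length = tf_ + tb_, width = w_px)
        break
      }
    }
  }
  fibres <- do.call(rbind, fibres)
  integrals <- mapply(capsule_integral, fibres$length, fibres$width)
  amplitude <- fa_target / sum(integrals)
  fibre_signal <- matrix(0, dimi[1], dimi[2])
  for (j in seq_len(nrow(fibres)))
    fibre_signal <- render_capsule(fibre_signal, fibres$x0[j], fibres$y0[j],
                                   fibres$x1[j], fibres$y1[j],
                                   fibres$width[j], amplitude)

  gfp <- (expression / n_px) * cell_mask
  stain <- fibre_signal + config$stain_diffuse * cell_mask
  dapi <- config$dapi_level * nucleus_mask

  truth <- list(cell_mask = cell_mask, nucleus_mask = nucleus_mask,
                fibre_signal = fibre_signal, fibres = fibres,
                expression = expression, area_px = n_px,
                area_um2 = n_px * ps^2, aspect_ratio = q, stellate = amp,
                n_fibres = nrow(fibres), fibre_thickness_um = w_px * ps,
                orientation_kappa = kappa, orientation_mu = mu,
                orientation_coherence = vm_resultant(kappa),
                nucleus_area_um2 = sum(nucleus_mask) * ps^2,
                fibre_amount = sum(fibre_signal),
                fibre_amount_analytic = fa_target,
                fibre_amplitude = amplitude)

  cell_image_set(apply_noise(gfp, config$noise),
                 apply_noise(stain, config$noise),
                 apply_noise(dapi, config$noise),
                 ps, id = id, truth = truth)
}

#' Generate a ground-truth-annotated synthetic population
#'
#' Draws per-cell expression from the configured lognormal law, maps it
#' through the transfer functions, renders one field of view per cell,
#' and returns the per-cell ground-truth table. Fully deterministic
#' under the config seed.
#'
#' @param config A [population_config()].
#' @param sink Optional `function(imgset, i)` called with each rendered
#'   [cell_image_set()] instead of accumulating them (memory-bounded
#'   streaming for large populations).
#' @return List with `images` (list of `CellImageSet`, or `NULL` when a
#'   sink is used) and `truth` (data.frame, one row per cell, with
#'   attributes `t1`, `t2`).
#' @examples
#' cfg <- population_config(n_cells = 2, image_size = c(96, 96),
#'                          noise = zero_noise(), seed = 7)
#' pop <- generate_population(cfg)
#' pop$truth$regime
#' @export
generate_population <- function(config, sink = NULL) {
  stopifnot(inherits(config, "population_config"))
  set.seed(config$seed)
  n <- config$n_cells
  expression <- 10^stats::rnorm(n, config$gfp_log_mean, config$gfp_log_sd)
  images <- if (is.null(sink)) vector("list", n) else NULL
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    cs <- simulate_cell(config, expression[i], id = sprintf("cell%04d", i))
    tr <- cs$truth
    rows[[i]] <- data.frame(
      id = cs$id, expression = tr$expression, area_um2 = tr$area_um2,
      area_px = tr$area_px, aspect_ratio = tr$aspect_ratio,
      stellate = tr$stellate, n_fibres = tr$n_fibres,
      fibre_thickness_um = tr$fibre_thickness_um,
      orientation_kappa = tr$orientation_kappa,
      orientation_coherence = tr$orientation_coherence,
      nucleus_area_um2 = tr$nucleus_area_um2,
      fibre_amount = tr$fibre_amount,
      regime = regime_label(tr$expression, config$t1, config$t2),
      stringsAsFactors = FALSE)
    if (is.null(sink)) images[[i]] <- cs else sink(cs, i)
  }
  truth <- do.call(rbind, rows)
  attr(truth, "t1") <- config$t1
  attr(truth, "t2") <- config$t2
  list(images = images, truth = truth)
}

# Regime of an expression value under thresholds (half-open intervals
# [0, t1), [t1, t2), [t2, Inf)).
regime_label <- function(expression, t1, t2) {
  ifelse(expression < t1, "no_effect",
         ifelse(expression < t2, "dose_response", "saturation"))
}

#' Synthetic immunostain raster from ground-truth masks
#'
#' Paints a protein stain (YAP- or cofilin-like) on known masks:
#' `background` outside the cell, `cytosol_level` inside, the nucleus
#' at `cytosol_level * nuclear_enrichment`, and `fibre_level` added on
#' fibre pixels. Ground truth for nuclear/cytosolic-ratio and
#' colocalization recovery tests.
#'
#' @param cell_mask,nucleus_mask,fibre_mask Logical masks (nucleus and
#'   fibre masks optional).
#' @param cytosol_level Cytosolic stain level, counts.
#' @param nuclear_enrichment Nuclear-to-cytosolic ratio to paint.
#' @param fibre_level Extra stain on fibre pixels, counts.
#' @param background Level outside the cell, counts.
#' @return Intensity matrix.
#' @export
simulate_protein_stain <- function(cell_mask, nucleus_mask = NULL,
                                   fibre_mask = NULL, cytosol_level = 50,
                                   nuclear_enrichment = 1, fibre_level = 0,
                                   background = 0) {
  assert_mask(cell_mask)
  img <- matrix(background, nrow(cell_mask), ncol(cell_mask))
  img[cell_mask] <- cytosol_level
  if (!is.null(nucleus_mask)) img[nucleus_mask] <- cytosol_level * nuclear_enrichment
  if (!is.null(fibre_mask)) img[fibre_mask] <- img[fibre_mask] + fibre_level
  img
}
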