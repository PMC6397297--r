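# Shared fixture builders: everything is generated in code at test time.

# Small noiseless configuration for fast rendering tests.
quiet_config <- function(n_cells = 1, seed = 1, ...) {
  population_config(n_cells = n_cells, noise = zero_noise(),
                    image_size = c(192, 192), seed = seed, ...)
}

# One isolated oblique fibre on a flat background; returns image and
# its exact parameters.
single_fibre_image <- function(dim = c(96, 96), angle_deg = 30, length = 70,
                               width = 4, amplitude = 100, background = 0) {
  ang <- angle_deg * pi / 180
  cx <- (dim[2] + 1) / 2; cy <- (dim[1] + 1) / 2
  img <- matrix(background, dim[1], dim[2])
  img <- render_capsule(img, cx - length / 2 * cos(ang),
                        cy - length / 2 * sin(ang),
                        cx + length / 2 * cos(ang),
                        cy + length / 2 * sin(ang), width, amplitude)
  list(img = img, angle = ang, length = length, width = width,
       amplitude = amplitude,
       fibre_sum = sum(img) - background * prod(dim))
}

# Solid ellipse mask (axes in px, axis-aligned).
ellipse_mask <- function(dim, a, b, cx = (dim[2] + 1) / 2,
                         cy = (dim[1] + 1) / 2) {
  x <- matrix(rep(seq_len(dim[2]), each = dim[1]), dim[1])
  y <- matrix(rep(seq_len(dim[1]), dim[2]), dim[1])
  ((x - cx) / a)^2 + ((y - cy) / b)^2 <= 1
}

# Synthetic dose-response bin series from a transfer function sampled
# on a log-uniform expression grid (bins built directly, no imaging).
synthetic_curve <- function(tf, n_bins = 40, lo = 1e3, hi = 1e7,
                            noise_cv = 0.05) {
  expr <- 10^seq(log10(lo), log10(hi), length.out = n_bins)
  value <- sample_parameter(transfer_function(tf$baseline, tf$plateau,
                                              tf$t1, tf$t2, noise_cv), expr)
  structure(data.frame(expression = expr, value = value,
                       lo = value, hi = value, n = rep(100L, n_bins)),
            descriptor = "synthetic", pooling = "gmean",
            class = c("DoseResponseCurve", "data.frame"))
}

# Independent direct-summation sample variance (oracle for RoV tests).
var_oracle <- function(x) {
  n <- length(x)
  m <- sum(x) / n
  sum((x - m)^2) / (n - 1)
}

rov_oracle <- function(d, N, log = TRUE) {
  if (log) d <- base::log(d)
  n <- length(d)
  sapply((N + 1):(n - N), function(i) {
    tr <- var_oracle(d[(i - N):(i - 1)])
    if (tr == 0) NA_real_ else var_oracle(d[(i + 1):(i + N)]) / tr
  })
}
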