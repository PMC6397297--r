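# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

gmean <- function(x) exp(mean(log(x)))

gsd <- function(x) exp(stats::sd(log(x)))

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' @noRd
assert_mask <- function(x, name = deparse(substitute(x))) {
  if (!is.matrix(x) || !is.logical(x))
    stop(sprintf("'%s' must be a logical matrix", name), call. = FALSE)
  x
}

# Pixel-centre coordinate grids; x = column index, y = row index.
# Angles are measured from the +x axis towards +y (i.e. downwards on
# screen), in [0, pi) for axial quantities.
coord_grid <- function(dim) {
  list(x = matrix(rep(seq_len(dim[2]), each = dim[1]), dim[1], dim[2]),
       y = matrix(rep(seq_len(dim[1]), dim[2]), dim[1], dim[2]))
}

# Largest connected component of a logical mask (8-connectivity).
largest_component <- function(mask) {
  lab <- EBImage::bwlabel(mask)
  if (max(lab) == 0L) return(mask & FALSE)
  counts <- tabulate(lab[lab > 0])
  lab == which.max(counts)
}

disc_brush <- function(radius) {
  EBImage::makeBrush(2L * as.integer(radius) + 1L, shape = "disc")
}

# Grayscale morphological opening on a counts-valued matrix (EBImage
# treats bare matrices as binary; grayscale morphology needs a [0,1]
# Image).
gray_opening <- function(x, brush) {
  mx <- max(x)
  if (mx <= 0) return(x)
  out <- EBImage::opening(EBImage::Image(x / mx), brush)
  matrix(as.numeric(EBImage::imageData(out)) * mx, nrow(x), ncol(x))
}

# Grayscale dilation (local maximum) on a counts-valued matrix.
gray_dilate <- function(x, brush) {
  mx <- max(x)
  if (mx <= 0) return(x)
  out <- EBImage::dilate(EBImage::Image(x / mx), brush)
  matrix(as.numeric(EBImage::imageData(out)) * mx, nrow(x), ncol(x))
}

# gblur whose kernel is clipped to the image size (EBImage errors when
# the filter exceeds the image).
safe_gblur <- function(x, sigma) {
  r <- 2L * as.integer(ceiling(3 * sigma)) + 1L
  mx <- min(dim(x))
  if (r > mx) r <- if (mx %% 2L == 0L) mx - 1L else mx
  EBImage::gblur(x, sigma = sigma, radius = r)
}

# Bounding box of a mask, padded and clipped to the image.
mask_bbox <- function(mask, pad = 0L) {
  w <- which(mask, arr.ind = TRUE)
  if (nrow(w) == 0L) return(NULL)
  list(r = c(max(1L, min(w[, 1]) - pad), min(nrow(mask), max(w[, 1]) + pad)),
       c = c(max(1L, min(w[, 2]) - pad), min(ncol(mask), max(w[, 2]) + pad)))
}

# ---- circular statistics on axial (undirected) angles -----------------------

# Resultant length of doubled angles, optionally weighted: the standard
# axial-coherence statistic in [0, 1].
axial_coherence <- function(theta, w = NULL) {
  if (length(theta) == 0L) return(NA_real_)
  if (is.null(w)) w <- rep(1, length(theta))
  sw <- sum(w)
  if (sw <= 0) return(NA_real_)
  sqrt(sum(w * cos(2 * theta))^2 + sum(w * sin(2 * theta))^2) / sw
}

# Mean axial direction in [0, pi).
axial_mean <- function(theta, w = NULL) {
  if (is.null(w)) w <- rep(1, length(theta))
  (atan2(sum(w * sin(2 * theta)), sum(w * cos(2 * theta))) / 2) %% pi
}

# von Mises sampler (Best & Fisher rejection); kappa = 0 falls back to
# the uniform distribution on the circle.
rvonmises <- function(n, mu, kappa) {
  if (kappa < 1e-8) return(stats::runif(n, -pi, pi) + mu)
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  for (i in seq_len(n)) {
    repeat {
      u <- stats::runif(3)
      z <- cos(pi * u[1])
      f <- (1 + r * z) / (r + z)
      cc <- kappa * (r - f)
      if (cc * (2 - cc) - u[2] > 0 || log(cc / u[2]) + 1 - cc >= 0) {
        out[i] <- sign(u[3] - 0.5) * acos(f)
        break
      }
    }
  }
  out + mu
}

# Expected resultant length of a von Mises with concentration kappa.
vm_resultant <- function(kappa) {
  ifelse(kappa < 1e-8, 0,
         besselI(kappa, 1, expon.scaled = TRUE) /
           besselI(kappa, 0, expon.scaled = TRUE))
}

# ---- mask shape moments -----------------------------------------------------

# Centroid and best-fit-ellipse axes of a mask from second-order central
# moments (the classical equivalent-ellipse construction).
mask_moments <- function(mask) {
  w <- which(mask, arr.ind = TRUE)
  n <- nrow(w)
  if (n == 0L) stop("empty mask", call. = FALSE)
  y <- w[, 1]; x <- w[, 2]
  cx <- mean(x); cy <- mean(y)
  # + 1/12 per axis: a pixel is a unit square, not a point
  mxx <- mean((x - cx)^2) + 1 / 12
  myy <- mean((y - cy)^2) + 1 / 12
  mxy <- mean((x - cx) * (y - cy))
  tr <- mxx + myy
  dd <- sqrt((mxx - myy)^2 + 4 * mxy^2)
  l1 <- (tr + dd) / 2
  l2 <- (tr - dd) / 2
  list(cx = cx, cy = cy, n = n,
       major = 4 * sqrt(l1), minor = 4 * sqrt(pmax(l2, 0)),
       theta = (atan2(2 * mxy, mxx - myy) / 2) %% pi)
}

# 4-connected boundary-edge count: number of mask/background pixel edges
# (image border counts as background). A consistent, comparable perimeter
# estimate when applied to both a mask and its convex hull.
edge_perimeter <- function(mask) {
  m <- mask
  padded <- matrix(FALSE, nrow(m) + 2L, ncol(m) + 2L)
  padded[2:(nrow(m) + 1L), 2:(ncol(m) + 1L)] <- m
  up <- padded[1:(nrow(padded) - 1L), ] & !padded[2:nrow(padded), ]
  dn <- !padded[1:(nrow(padded) - 1L), ] & padded[2:nrow(padded), ]
  lf <- padded[, 1:(ncol(padded) - 1L)] & !padded[, 2:ncol(padded)]
  rt <- !padded[, 1:(ncol(padded) - 1L)] & padded[, 2:ncol(padded)]
  sum(up) + sum(dn) + sum(lf) + sum(rt)
}

# Rasterize the convex hull of a mask (pixel centres inside the hull
# polygon, vertices inclusive).
convex_hull_mask <- function(mask) {
  w <- which(mask, arr.ind = TRUE)
  if (nrow(w) < 3L) return(mask)
  pts <- cbind(w[, 2], w[, 1])            # (x, y)
  h <- grDevices::chull(pts)
  poly <- pts[h, , drop = FALSE]
  g <- coord_grid(dim(mask))
  inside <- point_in_polygon(g$x, g$y, poly[, 1], poly[, 2])
  matrix(inside, nrow(mask), ncol(mask)) | mask
}

# Even-odd rule point-in-polygon, vectorised over query points; points on
# an edge are treated as inside (tolerance-free for convex hulls of
# integer points queried at integer centres).
point_in_polygon <- function(px, py, vx, vy) {
  n <- length(vx)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    cross <- (vy[i] > py) != (vy[j] > py)
    xin <- px < (vx[j] - vx[i]) * (py - vy[i]) / (vy[j] - vy[i]) + vx[i]
    inside <- xor(inside, cross & xin)
    j <- i
  }
  inside
}

# ---- skeletonization --------------------------------------------------------

# Zhang-Suen thinning to a 1-px skeleton; vectorised over the image.
skeletonize <- function(mask) {
  m <- mask
  if (!any(m)) return(m)
  repeat {
    changed <- FALSE
    for (step in 1:2) {
      p <- ws_neighbours(m)
      bp <- p$p2 + p$p3 + p$p4 + p$p5 + p$p6 + p$p7 + p$p8 + p$p9
      ap <- (!p$p2 & p$p3) + (!p$p3 & p$p4) + (!p$p4 & p$p5) +
        (!p$p5 & p$p6) + (!p$p6 & p$p7) + (!p$p7 & p$p8) +
        (!p$p8 & p$p9) + (!p$p9 & p$p2)
      if (step == 1L) {
        cond <- !(p$p2 & p$p4 & p$p6) & !(p$p4 & p$p6 & p$p8)
      } else {
        cond <- !(p$p2 & p$p4 & p$p8) & !(p$p2 & p$p6 & p$p8)
      }
      del <- m & bp >= 2 & bp <= 6 & ap == 1 & cond
      if (any(del)) {
        m[del] <- FALSE
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  m
}

# 8-neighbourhood shifts (p2 = north, clockwise), zero-padded borders.
ws_neighbours <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  z <- matrix(FALSE, nr, nc)
  shift <- function(dr, dc) {
    out <- z
    rs <- max(1, 1 + dr):min(nr, nr + dr)
    cs <- max(1, 1 + dc):min(nc, nc + dc)
    out[rs, cs] <- m[rs - dr, cs - dc]
    out
  }
  list(p2 = shift(1, 0), p3 = shift(1, -1), p4 = shift(0, -1),
       p5 = shift(-1, -1), p6 = shift(-1, 0), p7 = shift(-1, 1),
       p8 = shift(0, 1), p9 = shift(1, 1))
}

# Geodesic length of a skeleton (px): orthogonal steps count 1, diagonal
# steps sqrt(2); diagonals bridged by an orthogonal pixel are not
# re-counted.
skeleton_length <- function(skel) {
  if (!any(skel)) return(0)
  nr <- nrow(skel); nc <- ncol(skel)
  orth <- sum(skel[-nr, ] & skel[-1, ]) + sum(skel[, -nc] & skel[, -1])
  # diagonal pair (r,c)-(r+1,c+1), bridges (r+1,c) and (r,c+1)
  d1 <- skel[-nr, -nc] & skel[-1, -1] & !skel[-1, -nc] & !skel[-nr, -1]
  # diagonal pair (r+1,c)-(r,c+1), bridges (r,c) and (r+1,c+1)
  d2 <- skel[-1, -nc] & skel[-nr, -1] & !skel[-nr, -nc] & !skel[-1, -1]
  orth + sqrt(2) * (sum(d1) + sum(d2))
}
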