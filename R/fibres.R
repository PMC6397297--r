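#' Segment stress fibres inside a cell
#'
#' Three-step fibre pipeline operating on the stain channel within the
#' cell mask:
#'
#' 1. *Initial segmentation* — a multi-scale ridge (curvilinear line)
#'    filter: at each scale the stain is Gaussian-smoothed and the
#'    smaller Hessian eigenvalue computed; the scale-normalized
#'    negative eigenvalue is maximised over scales and thresholded
#'    (Otsu within the cell, plus a relative floor). The response is
#'    computed on a copy whose exterior is in-painted with the cell's
#'    median level, so the cell edge itself carries no ridge.
#' 2. *Refinement* — candidates are re-grown to the local half-maximum
#'    brightness (half the local peak within a small disc, so the mask
#'    width tracks the true fibre width rather than the filter scale),
#'    then components whose skeleton is shorter than `min_length` px
#'    are removed.
#' 3. *Background determination and subtraction* — the diffuse
#'    (non-fibre) signal is estimated by a morphological opening at a
#'    scale larger than the widest fibre and subtracted to give the
#'    fibre brightness map.
#'
#' Local fibre orientation is the principal direction of the smoothed
#' structure tensor, rotated to lie along the ridge, in `[0, pi)` with
#' 0 = image x-axis (columns).
#'
#' @param stain Stain intensity matrix.
#' @param cell_mask Logical cell mask (non-empty).
#' @param scales Ridge filter smoothing scales, px.
#' @param min_length Minimum skeleton length per fibre component, px.
#' @param bg_radius Radius of the background-opening brush, px; must
#'   exceed the widest expected fibre half-width.
#' @param edge_erode Erosion radius applied to the cell mask before
#'   ridge thresholding, px.
#' @param tensor_sigma Structure-tensor integration scale, px.
#' @return A `FibreMaps` list: `fibre_mask`, `fibre_brightness`
#'   (background-subtracted, zero off-mask), `orientation` (radians,
#'   `NA` off-mask), `cell_mask`, `skeleton`, `labels` (integer
#'   component map) and `background` (estimated diffuse raster).
#'   A fibreless cell yields an empty `fibre_mask`.
#' @export
segment_fibres <- function(stain, cell_mask, scales = c(1, 2, 4),
                           min_length = 10, bg_radius = 8, edge_erode = 1,
                           tensor_sigma = 2.5) {
  assert_mask(cell_mask)
  if (!any(cell_mask)) stop("empty cell mask", call. = FALSE)
  dimi <- dim(stain)
  bb <- mask_bbox(cell_mask, pad = 2L * ceiling(max(scales)) + 4L)
  rs <- bb$r[1]:bb$r[2]; cs <- bb$c[1]:bb$c[2]
  st <- stain[rs, cs]
  cm <- cell_mask[rs, cs]

  # step 3 estimate first; brightness needs it and refinement uses it.
  # The exterior is in-painted with the cell's median level so the
  # opening sees no step at the cell edge (which would otherwise leak
  # low exterior values into the background estimate near the border).
  st_fill <- st
  st_fill[!cm] <- stats::median(st[cm])
  bg <- gray_opening(st_fill, disc_brush(bg_radius))
  resid <- pmax(st - bg, 0)
  resid[!cm] <- 0

  # step 1: multi-scale ridge response, computed on the in-painted
  # image so the cell edge itself carries no ridge and fibres running
  # close to the boundary are kept
  resp <- matrix(0, nrow(st), ncol(st))
  for (s in scales) {
    sm <- safe_gblur(st_fill, s)
    hx <- hessian_maps(sm)
    tr <- hx$xx + hx$yy
    dd <- sqrt((hx$xx - hx$yy)^2 + 4 * hx$xy^2)
    l2 <- (tr - dd) / 2
    resp <- pmax(resp, s^2 * pmax(-l2, 0))
  }
  region <- if (edge_erode > 0)
    EBImage::erode(cm, disc_brush(edge_erode)) > 0 else cm
  rin <- resp[region]
  empty <- function() fibre_maps_empty(dimi, cell_mask)
  if (length(rin) == 0L || max(rin) <= 0) return(empty())
  thr <- tryCatch(
    EBImage::otsu(EBImage::Image(matrix(rin / max(rin), 1)),
                  range = c(0, 1)) * max(rin),
    error = function(e) 0.5 * max(rin))
  cand <- resp > pmax(thr, 0.05 * max(rin)) & region
  if (!any(cand)) return(empty())

  # step 2: regrow candidates to the local half-maximum brightness
  # (local peak within a small disc, so crossings with doubled
  # intensity do not raise the threshold for neighbouring single
  # fibres), keeping only components connected to a ridge candidate
  locmax <- gray_dilate(resid, disc_brush(2))
  grown <- resid > 0.5 * locmax & resid > 0 &
    (EBImage::dilate(cand, disc_brush(2)) > 0) & cm
  if (!any(grown)) return(empty())
  gl <- EBImage::bwlabel(grown)
  keep <- unique(gl[cand & grown])
  keep <- keep[keep > 0]
  if (length(keep) == 0L) return(empty())
  refined <- matrix(gl %in% keep, nrow(gl)) & grown
  lab2 <- EBImage::bwlabel(refined)
  skel_all <- matrix(FALSE, nrow(st), ncol(st))
  keep_mask <- matrix(FALSE, nrow(st), ncol(st))
  for (j in seq_len(max(lab2))) {
    comp <- lab2 == j
    sk <- skeletonize(comp)
    if (skeleton_length(sk) >= min_length) {
      keep_mask <- keep_mask | comp
      skel_all <- skel_all | sk
    }
  }
  if (!any(keep_mask)) return(empty())

  # support mask: 1-px dilation of the half-max core, capturing the
  # anti-aliased intensity tails so fibre_amount conserves the rendered
  # signal; the core is kept for width measurement (FWHM convention)
  support <- (EBImage::dilate(keep_mask, EBImage::makeBrush(3, "box")) > 0) & cm

  theta <- structure_tensor_orientation(st_fill, tensor_sigma)

  embed <- function(x, fill) {
    out <- matrix(fill, dimi[1], dimi[2])
    out[rs, cs] <- x
    out
  }
  fibre_mask <- embed(support, FALSE)
  brightness <- embed(resid, 0)
  brightness[!fibre_mask] <- 0
  orientation <- embed(theta, NA_real_)
  orientation[!fibre_mask] <- NA_real_
  labels <- embed(EBImage::bwlabel(support), 0L)
  structure(list(fibre_mask = fibre_mask, fibre_brightness = brightness,
                 orientation = orientation, cell_mask = cell_mask,
                 core_mask = embed(keep_mask, FALSE),
                 skeleton = embed(skel_all, FALSE), labels = labels,
                 background = embed(bg, 0)),
            class = "FibreMaps")
}

fibre_maps_empty <- function(dimi, cell_mask) {
  z <- matrix(FALSE, dimi[1], dimi[2])
  structure(list(fibre_mask = z,
                 fibre_brightness = matrix(0, dimi[1], dimi[2]),
                 orientation = matrix(NA_real_, dimi[1], dimi[2]),
                 cell_mask = cell_mask, core_mask = z, skeleton = z,
                 labels = matrix(0L, dimi[1], dimi[2]),
                 background = matrix(0, dimi[1], dimi[2])),
            class = "FibreMaps")
}

# Second-derivative maps by central differences (replicated borders).
hessian_maps <- function(sm) {
  nr <- nrow(sm); nc <- ncol(sm)
  sh <- function(m, dr, dc) {
    ri <- clamp(seq_len(nr) - dr, 1, nr)
    ci <- clamp(seq_len(nc) - dc, 1, nc)
    m[ri, ci, drop = FALSE]
  }
  xx <- sh(sm, 0, 1) - 2 * sm + sh(sm, 0, -1)
  yy <- sh(sm, 1, 0) - 2 * sm + sh(sm, -1, 0)
  xy <- (sh(sm, 1, 1) + sh(sm, -1, -1) - sh(sm, 1, -1) - sh(sm, -1, 1)) / 4
  list(xx = xx, yy = yy, xy = xy)
}

# Ridge-aligned orientation from the smoothed structure tensor:
# dominant tensor eigenvector = gradient direction, fibre runs
# perpendicular to it. Angle in [0, pi), 0 = x-axis.
structure_tensor_orientation <- function(img, tensor_sigma = 2.5,
                                         grad_sigma = 1.5) {
  sm <- safe_gblur(img, grad_sigma)
  nr <- nrow(sm); nc <- ncol(sm)
  sh <- function(m, dr, dc) {
    ri <- clamp(seq_len(nr) - dr, 1, nr)
    ci <- clamp(seq_len(nc) - dc, 1, nc)
    m[ri, ci, drop = FALSE]
  }
  ix <- (sh(sm, 0, -1) - sh(sm, 0, 1)) / 2
  iy <- (sh(sm, -1, 0) - sh(sm, 1, 0)) / 2
  jxx <- safe_gblur(ix * ix, tensor_sigma)
  jyy <- safe_gblur(iy * iy, tensor_sigma)
  jxy <- safe_gblur(ix * iy, tensor_sigma)
  (0.5 * atan2(2 * jxy, jxx - jyy) + pi / 2) %% pi
}
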