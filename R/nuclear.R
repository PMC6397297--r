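#' Equal-area cytosolic annulus around the nucleus
#'
#' Grows the nucleus by successive 1-px dilations, collecting new
#' pixels that lie inside the cell and outside the nucleus, until the
#' collected count first reaches the nucleus pixel count; the final
#' ring is truncated deterministically (row-major order: by row, then
#' column) to give exactly equal counts. This realizes the standard
#' "annular region of equal size immediately adjacent to the nucleus"
#' used for nuclear/cytosolic ratios.
#'
#' @param nucleus_mask,cell_mask Logical masks; the nucleus must lie
#'   inside the cell.
#' @return An `AnnulusSpec` list with `nucleus_mask` and
#'   `annulus_mask` (equal pixel counts, disjoint, annulus within the
#'   cell).
#' @export
build_annulus <- function(nucleus_mask, cell_mask) {
  assert_mask(nucleus_mask); assert_mask(cell_mask)
  if (!any(nucleus_mask)) stop("empty nucleus mask", call. = FALSE)
  if (any(nucleus_mask & !cell_mask))
    stop("nucleus mask extends outside the cell mask", call. = FALSE)
  target <- sum(nucleus_mask)
  annulus <- nucleus_mask & FALSE
  current <- nucleus_mask
  collected <- 0L
  brush <- EBImage::makeBrush(3, "box")
  while (collected < target) {
    grown <- EBImage::dilate(current, brush) > 0
    ring <- grown & cell_mask & !nucleus_mask & !annulus
    n_new <- sum(ring)
    if (n_new == 0L)
      stop("cell too small to host an equal-area annulus", call. = FALSE)
    if (collected + n_new > target) {
      w <- which(ring, arr.ind = TRUE)
      keep <- w[order(w[, 1], w[, 2])[seq_len(target - collected)], ,
                drop = FALSE]
      ring <- ring & FALSE
      ring[keep] <- TRUE
      n_new <- target - collected
    }
    annulus <- annulus | ring
    collected <- collected + n_new
    current <- grown
  }
  structure(list(nucleus_mask = nucleus_mask, annulus_mask = annulus),
            class = "AnnulusSpec")
}

#' Nuclear-to-cytosolic stain ratio
#'
#' Mean stain intensity over the nucleus divided by the mean over the
#' equal-area adjacent cytosolic annulus — the standard readout for
#' nuclear translocation of mechanosensitive factors such as YAP.
#'
#' @param stain Stain intensity matrix.
#' @param spec An `AnnulusSpec` from [build_annulus()].
#' @return Positive scalar ratio.
#' @export
nuc_cyto_ratio <- function(stain, spec) {
  stopifnot(inherits(spec, "AnnulusSpec"))
  if (!any(spec$nucleus_mask) || !any(spec$annulus_mask))
    stop("empty mask in annulus spec", call. = FALSE)
  cyto <- mean(stain[spec$annulus_mask])
  if (cyto == 0) stop("degenerate cytosolic signal", call. = FALSE)
  mean(stain[spec$nucleus_mask]) / cyto
}

#' Mean stain intensity on fibre pixels
#'
#' Mean background-subtracted stain over the pixels previously
#' identified as fibre, quantifying colocalization of a stained protein
#' (e.g. cofilin or YAP) to the actin cytoskeleton. An empty fibre mask
#' yields `NA` (missing, not zero).
#'
#' @param stain Stain intensity matrix.
#' @param fibre_mask Logical fibre mask (from [segment_fibres()]).
#' @param background Background counts; when `NULL`, estimated as the
#'   median outside `cell_mask` (which must then be supplied).
#' @param cell_mask Optional cell mask for background estimation.
#' @return Mean counts, or `NA_real_` when no fibre pixels exist.
#' @export
fibre_colocalized_intensity <- function(stain, fibre_mask, background = NULL,
                                        cell_mask = NULL) {
  assert_mask(fibre_mask)
  if (!any(fibre_mask)) return(NA_real_)
  if (is.null(background)) {
    if (is.null(cell_mask))
      stop("supply 'background' or 'cell_mask' to estimate it", call. = FALSE)
    background <- stats::median(stain[!cell_mask])
  }
  mean(pmax(stain[fibre_mask] - background, 0))
}

#' Planar nucleus size and shape
#'
#' Projected area and best-fit-ellipse axes of the nucleus mask.
#'
#' @param dapi DAPI intensity matrix (shape reference only).
#' @param nucleus_mask Logical nucleus mask (non-empty).
#' @param pixel_size Micrometres per pixel.
#' @return List with `area` (um^2), `major`, `minor` (um) and
#'   `axis_ratio`.
#' @export
nucleus_descriptors <- function(dapi, nucleus_mask, pixel_size) {
  assert_mask(nucleus_mask)
  if (!any(nucleus_mask)) stop("empty nucleus mask", call. = FALSE)
  stopifnot(all(dim(dapi) == dim(nucleus_mask)), pixel_size > 0)
  m <- mask_moments(nucleus_mask)
  list(area = m$n * pixel_size^2,
       major = m$major * pixel_size,
       minor = m$minor * pixel_size,
       axis_ratio = m$major / max(m$minor, .Machine$double.eps))
}
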