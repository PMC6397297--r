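#' Per-cell morphometric descriptors
#'
#' Assembles the descriptor set for one segmented cell from its fibre
#' maps and masks:
#'
#' * `area` — cell mask pixel count times `pixel_size^2` (um^2).
#' * `aspect_ratio` — major/minor axis of the mask's best-fit ellipse
#'   (second-order moments), >= 1.
#' * `stellate_factor` — mask perimeter over convex-hull perimeter,
#'   minus 1 (0 for a convex cell; filopodial protrusions raise it).
#' * `fibre_amount` — summed background-subtracted brightness over
#'   fibre pixels (counts): the amount of stained protein organized in
#'   fibres.
#' * `fibre_thickness` — twice the mean distance-transform value on the
#'   fibre skeleton, less a half-pixel edge-discretization correction
#'   (um).
#' * `fibre_length` — mean geodesic skeleton length per fibre
#'   component (um).
#' * `orientation_coherence` — brightness-weighted resultant length of
#'   doubled fibre orientations, in [0, 1] (fibres are axial data).
#' * `radiality` — brightness-weighted mean of `cos^2(theta - phi)`
#'   where `phi` is the radial direction from the cell centroid, in
#'   [0, 1] (1 = fibres point at the centroid).
#' * nucleus descriptors (when a nucleus mask is given) — projected
#'   area (um^2) and equivalent-ellipse axes (um).
#' * `total_gfp` (when the GFP channel is given) — see [total_gfp()].
#'
#' A fibreless cell gets `fibre_amount = 0` and `NA` for the remaining
#' fibre descriptors, flagged by `has_fibres = FALSE`.
#'
#' @param maps A `FibreMaps` from [segment_fibres()].
#' @param pixel_size Micrometres per pixel.
#' @param nucleus_mask Optional logical nucleus mask.
#' @param gfp Optional GFP channel for the expression surrogate.
#' @param gfp_background Optional background for [total_gfp()].
#' @return One-row data.frame (a cell record).
#' @export
compute_descriptors <- function(maps, pixel_size, nucleus_mask = NULL,
                                gfp = NULL, gfp_background = NULL) {
  stopifnot(inherits(maps, "FibreMaps"), pixel_size > 0)
  cell <- maps$cell_mask
  if (!any(cell)) stop("empty cell mask", call. = FALSE)
  mom <- mask_moments(cell)
  area <- mom$n * pixel_size^2
  aspect <- mom$major / max(mom$minor, .Machine$double.eps)

  hull <- convex_hull_mask(cell)
  stellate <- edge_perimeter(cell) / edge_perimeter(hull) - 1

  has_fibres <- any(maps$fibre_mask)
  if (has_fibres) {
    fibre_amount <- sum(maps$fibre_brightness)
    dm <- EBImage::distmap(maps$core_mask)
    thick_px <- 2 * mean(dm[maps$skeleton & maps$core_mask]) - 0.25
    labs <- maps$labels
    lens <- vapply(seq_len(max(labs)), function(j)
      skeleton_length(maps$skeleton & labs == j), numeric(1))
    lens <- lens[lens > 0]
    mean_len <- if (length(lens)) mean(lens) else NA_real_
    idx <- which(maps$fibre_mask)
    th <- maps$orientation[idx]
    b <- maps$fibre_brightness[idx]
    coher <- axial_coherence(th, b)
    rc <- arrayInd(idx, dim(cell))
    phi <- atan2(rc[, 1] - mom$cy, rc[, 2] - mom$cx)
    radial <- sum(b * cos(th - phi)^2) / sum(b)
  } else {
    fibre_amount <- 0
    thick_px <- NA_real_; mean_len <- NA_real_
    coher <- NA_real_; radial <- NA_real_
  }

  rec <- data.frame(
    area = area, aspect_ratio = aspect, stellate_factor = stellate,
    fibre_amount = fibre_amount,
    fibre_thickness = thick_px * pixel_size,
    fibre_length = mean_len * pixel_size,
    orientation_coherence = coher, radiality = radial,
    has_fibres = has_fibres)

  if (!is.null(nucleus_mask) && any(nucleus_mask)) {
    nm <- mask_moments(nucleus_mask)
    rec$nucleus_area <- nm$n * pixel_size^2
    rec$nucleus_major <- nm$major * pixel_size
    rec$nucleus_minor <- nm$minor * pixel_size
  } else {
    rec$nucleus_area <- NA_real_
    rec$nucleus_major <- NA_real_
    rec$nucleus_minor <- NA_real_
  }
  if (!is.null(gfp))
    rec$total_gfp <- total_gfp(gfp, cell, gfp_background)
  rec
}

#' Quantify one field of view end to end
#'
#' Segmentation, fibre pipeline and descriptor assembly for a single
#' [cell_image_set()]: the per-cell record used to build dose-response
#' curves.
#'
#' @param images A [cell_image_set()].
#' @param ... Passed to [segment_fibres()].
#' @return One-row data.frame with an `id` column, total GFP and all
#'   descriptors.
#' @export
quantify_cell <- function(images, ...) {
  stopifnot(inherits(images, "CellImageSet"))
  masks <- segment_cell(images)
  maps <- segment_fibres(images$stain, masks$cell_mask, ...)
  rec <- compute_descriptors(maps, images$pixel_size,
                             nucleus_mask = masks$nucleus_mask,
                             gfp = images$gfp)
  cbind(data.frame(id = images$id, stringsAsFactors = FALSE), rec)
}

#' Quantify a list of fields of view
#'
#' @param image_sets List of [cell_image_set()] objects.
#' @param ... Passed to [quantify_cell()].
#' @return data.frame, one row per successfully quantified cell; cells
#'   failing segmentation are dropped with a warning naming them.
#' @export
quantify_images <- function(image_sets, ...) {
  rows <- lapply(image_sets, function(cs) {
    tryCatch(quantify_cell(cs, ...), error = function(e) {
      warning(sprintf("cell '%s' skipped: %s", cs$id, conditionMessage(e)),
              call. = FALSE)
      NULL
    })
  })
  do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
}
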