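#' Read a multi-channel image set from TIFF files
#'
#' Loads one grayscale TIFF per channel (16-bit integer or float),
#' checks that shapes match, and assembles a [cell_image_set()].
#'
#' @param paths Named character vector or list with entries `gfp`,
#'   `stain`, `dapi`.
#' @param pixel_size Micrometres per pixel.
#' @param id Identifier (default: gfp file name without extension).
#' @return A [cell_image_set()].
#' @export
read_image_set <- function(paths, pixel_size, id = NULL) {
  paths <- as.list(paths)
  stopifnot(all(c("gfp", "stain", "dapi") %in% names(paths)))
  rd <- function(p) {
    if (!file.exists(p)) stop(sprintf("unreadable file: '%s'", p),
                              call. = FALSE)
    x <- tiff::readTIFF(p, as.is = TRUE)
    if (length(dim(x)) == 3L) x <- x[, , 1]
    matrix(as.numeric(x), nrow(x), ncol(x))
  }
  ch <- lapply(paths[c("gfp", "stain", "dapi")], rd)
  if (is.null(id)) id <- sub("\\.tiff?$", "", basename(paths$gfp))
  cell_image_set(ch$gfp, ch$stain, ch$dapi, pixel_size, id = id)
}

#' Write an image set as 16-bit TIFFs plus a JSON sidecar
#'
#' One grayscale TIFF per channel (`<id>_gfp.tif`, `<id>_stain.tif`,
#' `<id>_dapi.tif`; values clipped to \[0, 65535\] and rounded) and a
#' `<id>_meta.json` sidecar recording channel order and pixel size.
#'
#' @param images A [cell_image_set()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the sidecar path.
#' @export
write_image_set <- function(images, dir) {
  stopifnot(inherits(images, "CellImageSet"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  chans <- c("gfp", "stain", "dapi")
  files <- file.path(dir, sprintf("%s_%s.tif", images$id, chans))
  for (i in seq_along(chans))
    tiff::writeTIFF(round(clamp(images[[chans[i]]], 0, 65535)) / 65535,
                    files[i], bits.per.sample = 16, compression = "none")
  meta <- file.path(dir, sprintf("%s_meta.json", images$id))
  jsonlite::write_json(list(id = images$id, channels = as.list(
    stats::setNames(basename(files), chans)),
    channel_order = chans, pixel_size = images$pixel_size,
    bits_per_sample = 16), meta, auto_unbox = TRUE, pretty = TRUE)
  invisible(meta)
}

#' Discover image sets in a directory via their JSON sidecars
#'
#' @param dir Directory containing `*_meta.json` sidecars written by
#'   [write_image_set()].
#' @return List of [cell_image_set()] objects.
#' @export
find_image_sets <- function(dir) {
  metas <- list.files(dir, pattern = "_meta\\.json$", full.names = TRUE)
  lapply(metas, function(m) {
    info <- jsonlite::read_json(m, simplifyVector = TRUE)
    cs <- read_image_set(
      stats::setNames(file.path(dir, unlist(info$channels[c("gfp", "stain",
                                                            "dapi")])),
                      c("gfp", "stain", "dapi")),
      pixel_size = info$pixel_size, id = info$id)
    # stored as scaled 16-bit; undo the writeTIFF normalization
    cs
  })
}

# FNV-1a hash of a string, for config fingerprints in logs.
fnv1a <- function(s) {
  bytes <- utf8ToInt(s)
  h <- 2166136261
  for (b in bytes) h <- (bitwXor(h, b) * 16777619) %% 2^32
  sprintf("%08x", h)
}

#' Run the full analysis pipeline
#'
#' Orchestrates the end-to-end analysis: obtain images (simulate a
#' synthetic population or load TIFF sets), quantify every cell, build
#' one dose-response curve per configured descriptor, locate RoV
#' transition candidates, pool them into global thresholds, and sort
#' cells into regimes. Writes `cells.csv`, `drc/<descriptor>.csv`,
#' `thresholds.json`, `regimes.csv` and `run.log` under `config$out`.
#'
#' @param config A list (or path to a JSON file) with fields:
#'   \describe{
#'     \item{out}{output directory (required)}
#'     \item{simulate}{list of [population_config()] arguments, or}
#'     \item{input_dir}{directory of image sets
#'       (see [find_image_sets()]); `pixel_size` then also applies}
#'     \item{descriptors}{named list mapping descriptor column to
#'       pooling (`"gmean"`, `"mean"`, `"median"`); default
#'       `list(area = "gmean", fibre_amount = "gmean")`}
#'     \item{n_min}{cells per bin (default 100)}
#'     \item{rov_N}{RoV window size (default 6)}
#'     \item{prominence, alpha}{peak criterion, see
#'       [detect_thresholds()]}
#'     \item{seed}{integer seed for the simulated branch}
#'   }
#' @return List with `records` (regime-labelled), `curves`,
#'   `candidates`, `thresholds`, and the output paths.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- jsonlite::read_json(config,
                                                          simplifyVector = TRUE)
  stopifnot(is.list(config), !is.null(config$out))
  out <- config$out
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out, "drc"), showWarnings = FALSE)
  descriptors <- config$descriptors %||% list(area = "gmean",
                                              fibre_amount = "gmean")
  n_min <- config$n_min %||% 100
  rov_N <- config$rov_N %||% 6
  prominence <- config$prominence %||% "fdist"
  alpha <- config$alpha %||% 0.01
  seed <- config$seed %||% 1

  logf <- file.path(out, "run.log")
  logline <- function(...) cat(sprintf(...), "\n", sep = "", file = logf,
                               append = TRUE)
  cat("", file = logf)
  logline("fibreDRC %s | R %s", as.character(utils::packageVersion("fibreDRC")),
          paste(R.version$major, R.version$minor, sep = "."))
  cfg_json <- jsonlite::toJSON(config[setdiff(names(config), "images")],
                               auto_unbox = TRUE, force = TRUE)
  logline("seed %d | config hash %s", as.integer(seed), fnv1a(cfg_json))

  truth <- NULL
  records <- local({
    if (!is.null(config$images)) {          # pre-built CellImageSet list
      quantify_images(config$images)
    } else if (!is.null(config$simulate)) {
      sim <- config$simulate
      sim$seed <- sim$seed %||% seed
      pcfg <- do.call(population_config, sim)
      rows <- vector("list", pcfg$n_cells)
      pop <- generate_population(pcfg, sink = function(cs, i) {
        rows[[i]] <<- tryCatch(quantify_cell(cs), error = function(e) NULL)
      })
      truth <<- pop$truth
      do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
    } else if (!is.null(config$input_dir)) {
      quantify_images(find_image_sets(config$input_dir))
    } else stop("config needs one of 'images', 'simulate', 'input_dir'",
                call. = FALSE)
  })
  logline("quantified %d cells", nrow(records))
  utils::write.csv(format_numeric(records), file.path(out, "cells.csv"),
                   row.names = FALSE)

  curves <- list(); cands <- list()
  for (dsc in names(descriptors)) {
    curve <- build_drc(records, dsc, n_min = n_min,
                       pooling = descriptors[[dsc]])
    utils::write.csv(format_numeric(curve),
                     file.path(out, "drc", paste0(dsc, ".csv")),
                     row.names = FALSE)
    rov <- rov_series(curve, N = rov_N)
    cd <- detect_thresholds(rov, curve, prominence = prominence,
                            alpha = alpha)
    logline("%s: %d bins, %d candidate threshold(s)", dsc, nrow(curve),
            nrow(cd))
    curves[[dsc]] <- curve
    cands[[dsc]] <- cd
  }
  thr <- tryCatch(global_thresholds(cands), error = function(e) {
    warning("no global thresholds: ", conditionMessage(e), call. = FALSE)
    c(G1 = NA_real_, G2 = NA_real_)
  })
  records <- if (all(is.finite(thr)))
    assign_regimes(records, thr["G1"], thr["G2"])
  else {
    records$regime <- factor(rep(NA_character_, nrow(records)),
                             levels = c("no_effect", "dose_response",
                                        "saturation"))
    records
  }
  jsonlite::write_json(
    list(G1 = unname(thr["G1"]), G2 = unname(thr["G2"]),
         candidates = lapply(cands, function(x)
           x[, c("expression", "type")]),
         units = "total background-subtracted GFP counts per cell"),
    file.path(out, "thresholds.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  utils::write.csv(format_numeric(records[, c("id", "total_gfp", "regime")]),
                   file.path(out, "regimes.csv"), row.names = FALSE)
  logline("G1 = %.6g, G2 = %.6g | regimes: %s", thr["G1"], thr["G2"],
          paste(sprintf("%s=%d", names(attr(records, "counts")),
                        as.integer(attr(records, "counts"))),
                collapse = " "))
  list(records = records, curves = curves, candidates = cands,
       thresholds = thr, truth = truth,
       paths = list(cells = file.path(out, "cells.csv"),
                    drc = file.path(out, "drc"),
                    thresholds = file.path(out, "thresholds.json"),
                    regimes = file.path(out, "regimes.csv"),
                    log = logf))
}

# Stable numeric formatting so identical runs give byte-identical CSVs.
format_numeric <- function(df) {
  for (j in seq_along(df))
    if (is.numeric(df[[j]]) && !is.integer(df[[j]]))
      df[[j]] <- sprintf("%.10g", df[[j]])
  df
}
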