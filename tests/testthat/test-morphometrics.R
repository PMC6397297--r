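test_that("segmentation recovers the rendered cell and nucleus", {
  cfg <- quiet_config(seed = 5)
  set.seed(17)
  cs <- simulate_cell(cfg, 1e6)
  masks <- segment_cell(cs)
  truth <- cs$truth$cell_mask
  jaccard <- sum(masks$cell_mask & truth) / sum(masks$cell_mask | truth)
  expect_gt(jaccard, 0.95)
  # nucleus is contained in the cell
  expect_true(all(!masks$nucleus_mask | masks$cell_mask))
  nj <- sum(masks$nucleus_mask & cs$truth$nucleus_mask) /
    sum(masks$nucleus_mask | cs$truth$nucleus_mask)
  expect_gt(nj, 0.9)
})

test_that("a blank field is rejected as empty", {
  z <- matrix(0, 96, 96)
  blank <- cell_image_set(z, z, z, pixel_size = 0.65)
  expect_error(segment_cell(blank), "empty field")
})

test_that("total GFP implements background-subtracted summation", {
  img <- matrix(10, 10, 10)
  mask <- matrix(FALSE, 10, 10); mask[1:2, 1:5] <- TRUE   # 10 px
  img[mask] <- 50
  expect_equal(total_gfp(img, mask, background = 10), 400)
  expect_equal(total_gfp(matrix(7, 5, 5), matrix(TRUE, 5, 5), background = 7),
               0)
  expect_error(total_gfp(img, matrix(FALSE, 10, 10)), "empty")
  # default background: median outside the mask
  expect_equal(total_gfp(img, mask), 400)
})

test_that("noiseless synthetic cell recovers its true expression", {
  cfg <- quiet_config(seed = 2)
  set.seed(8)
  cs <- simulate_cell(cfg, 2e6)
  masks <- segment_cell(cs)
  expect_equal(total_gfp(cs$gfp, masks$cell_mask), 2e6, tolerance = 0.01)
})

test_that("a uniform cell yields an empty fibre mask and zero amount", {
  mask <- ellipse_mask(c(96, 96), 30, 25)
  stain <- matrix(0, 96, 96); stain[mask] <- 50
  maps <- segment_fibres(stain, mask)
  expect_false(any(maps$fibre_mask))
  rec <- compute_descriptors(maps, 0.65)
  expect_equal(rec$fibre_amount, 0)
  expect_false(rec$has_fibres)
  expect_true(is.na(rec$fibre_thickness))
})

test_that("an isolated rendered fibre is recovered with its geometry", {
  sf <- single_fibre_image(angle_deg = 30, width = 4, amplitude = 100)
  maps <- segment_fibres(sf$img, matrix(TRUE, 96, 96), edge_erode = 0)
  expect_equal(max(maps$labels), 1)   # one skeleton component
  rec <- compute_descriptors(maps, 1)
  ang <- fibreDRC:::axial_mean(maps$orientation[maps$fibre_mask],
                               maps$fibre_brightness[maps$fibre_mask])
  expect_lt(abs(ang - sf$angle) * 180 / pi, 3)
  expect_gt(rec$orientation_coherence, 0.95)
  expect_gte(rec$fibre_thickness, 3.5)
  expect_lte(rec$fibre_thickness, 4.5)
  # fibre amount captures at least 90% of the rendered signal
  expect_gt(rec$fibre_amount, 0.9 * sf$fibre_sum)
  expect_lte(rec$fibre_amount, sum(sf$img) + 1e-9)
})

test_that("two crossing fibres produce a bimodal orientation map", {
  img <- matrix(0, 96, 96)
  a1 <- atan2(30, 76); a2 <- atan2(-70, 50) %% pi
  img <- render_capsule(img, 10, 30, 86, 60, 4, 100)
  img <- render_capsule(img, 20, 80, 70, 10, 4, 100)
  maps <- segment_fibres(img, matrix(TRUE, 96, 96), edge_erode = 0)
  th <- maps$orientation[maps$fibre_mask] * 180 / pi
  expect_gt(sum(maps$fibre_brightness), 0.85 * sum(img))
  h <- hist(th, breaks = seq(0, 180, 10), plot = FALSE)
  modes <- h$mids[order(h$counts, decreasing = TRUE)][1:2]
  tru <- sort(c(a1, a2) * 180 / pi)
  expect_lt(min(abs(sort(modes) - tru)), 5)
  expect_lt(max(abs(sort(modes) - tru)), 5)
})

test_that("descriptor formulas agree with shape moments on known masks", {
  # 100 x 50 solid rectangle: aspect ratio 2 within the ellipse-fit slack
  mask <- matrix(FALSE, 160, 160)
  mask[31:130, 51:100] <- TRUE
  maps <- fibreDRC:::fibre_maps_empty(c(160, 160), mask)
  rec <- compute_descriptors(maps, 1)
  expect_equal(rec$aspect_ratio, 2, tolerance = 0.05)
  expect_equal(rec$area, 100 * 50)
  # solid disk: convex and isotropic
  dmask <- ellipse_mask(c(120, 120), 40, 40)
  dmaps <- fibreDRC:::fibre_maps_empty(c(120, 120), dmask)
  drec <- compute_descriptors(dmaps, 1)
  expect_equal(drec$aspect_ratio, 1, tolerance = 0.02)
  expect_lt(abs(drec$stellate_factor), 0.02)
})

test_that("descriptors are rotation-equivariant and follow the scale law", {
  cfg <- quiet_config(seed = 6)
  set.seed(23)
  cs <- simulate_cell(cfg, 3e6)
  masks <- segment_cell(cs)
  maps <- segment_fibres(cs$stain, masks$cell_mask)
  rec <- compute_descriptors(maps, cfg$pixel_size,
                             nucleus_mask = masks$nucleus_mask)
  rot90 <- function(m) t(m)[, nrow(m):1, drop = FALSE]
  csr <- cell_image_set(rot90(cs$gfp), rot90(cs$stain), rot90(cs$dapi),
                        cs$pixel_size, id = "rot")
  masksr <- segment_cell(csr)
  mapsr <- segment_fibres(csr$stain, masksr$cell_mask)
  recr <- compute_descriptors(mapsr, cfg$pixel_size,
                              nucleus_mask = masksr$nucleus_mask)
  for (f in c("area", "aspect_ratio", "stellate_factor", "fibre_amount",
              "fibre_thickness"))
    expect_equal(recr[[f]], rec[[f]], tolerance = 0.02)
  a0 <- fibreDRC:::axial_mean(maps$orientation[maps$fibre_mask],
                              maps$fibre_brightness[maps$fibre_mask])
  a1 <- fibreDRC:::axial_mean(mapsr$orientation[mapsr$fibre_mask],
                              mapsr$fibre_brightness[mapsr$fibre_mask])
  dd <- abs(((a1 - a0) %% pi) - pi / 2)
  expect_lt(min(dd, pi - dd + pi / 2 - pi / 2), 0.1)
  # scale law: doubling pixel size doubles lengths, quadruples area
  rec2 <- compute_descriptors(maps, 2 * cfg$pixel_size,
                              nucleus_mask = masks$nucleus_mask)
  expect_equal(rec2$area, 4 * rec$area)
  expect_equal(rec2$fibre_thickness, 2 * rec$fibre_thickness)
  expect_equal(rec2$fibre_length, 2 * rec$fibre_length)
  expect_equal(rec2$fibre_amount, rec$fibre_amount)
})

test_that("measured area ranks with true area across a noiseless population", {
  cfg <- quiet_config(n_cells = 40, seed = 44)
  pop <- generate_population(cfg)
  rec <- quantify_images(pop$images)
  m <- match(rec$id, pop$truth$id)
  rho <- stats::cor(rec$area, pop$truth$area_um2[m], method = "spearman")
  expect_gt(rho, 0.99)
})
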