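test_that("annulus construction gives equal-count adjacent rings", {
  cell <- ellipse_mask(c(128, 128), 50, 45)
  nuc <- ellipse_mask(c(128, 128), 12, 9)
  spec <- build_annulus(nuc, cell)
  expect_equal(sum(spec$annulus_mask), sum(nuc))
  expect_false(any(spec$annulus_mask & nuc))
  expect_true(all(!spec$annulus_mask | cell))
  # adjacency: every annulus pixel within the first few dilation rings
  # (enough rings to hold the nucleus area around its perimeter)
  grown <- nuc
  for (i in 1:6) grown <- EBImage::dilate(grown, EBImage::makeBrush(3, "box")) > 0
  expect_true(all(!spec$annulus_mask | grown))
  # determinism
  spec2 <- build_annulus(nuc, cell)
  expect_identical(spec$annulus_mask, spec2$annulus_mask)
})

test_that("annulus construction handles boundary cases per the rule", {
  # nucleus touching the cell border: terminates or errors, never hangs
  cell <- ellipse_mask(c(64, 64), 14, 14)
  nuc <- ellipse_mask(c(64, 64), 12, 12)
  expect_error(build_annulus(nuc, cell), "too small")
  expect_error(build_annulus(nuc & FALSE, cell), "empty")
  expect_error(build_annulus(cell, nuc), "outside")
})

test_that("annulus stays disjoint from the nucleus over random geometries", {
  set.seed(314)
  for (i in 1:100) {
    dim <- c(96, 96)
    cell <- ellipse_mask(dim, runif(1, 25, 40), runif(1, 22, 38))
    nuc <- ellipse_mask(dim, runif(1, 5, 12), runif(1, 4, 10),
                        cx = 48 + runif(1, -6, 6), cy = 48 + runif(1, -6, 6))
    nuc <- nuc & cell
    spec <- tryCatch(build_annulus(nuc, cell), error = function(e) NULL)
    if (is.null(spec)) next
    expect_false(any(spec$annulus_mask & nuc))
    expect_equal(sum(spec$annulus_mask), sum(nuc))
  }
})

test_that("nuclear/cytosolic ratio recovers painted enrichment", {
  cell <- ellipse_mask(c(128, 128), 50, 45)
  nuc <- ellipse_mask(c(128, 128), 12, 9)
  spec <- build_annulus(nuc, cell)
  # uniform image -> ratio 1
  expect_equal(nuc_cyto_ratio(matrix(37, 128, 128), spec), 1)
  # hand-built 2:1 case
  img <- matrix(0, 128, 128)
  img[nuc] <- 80; img[spec$annulus_mask] <- 40
  expect_equal(nuc_cyto_ratio(img, spec), 2)
  # generator-set enrichment factor, zero noise
  for (e in c(0.5, 1.6, 3)) {
    st <- simulate_protein_stain(cell, nuc, cytosol_level = 50,
                                 nuclear_enrichment = e)
    expect_equal(nuc_cyto_ratio(st, spec), e, tolerance = 0.02)
  }
  # scale invariance
  st <- simulate_protein_stain(cell, nuc, cytosol_level = 50,
                               nuclear_enrichment = 1.7)
  expect_equal(nuc_cyto_ratio(st * 13.7, spec), nuc_cyto_ratio(st, spec),
               tolerance = 1e-12)
  expect_error(nuc_cyto_ratio(matrix(0, 128, 128), spec), "degenerate")
})

test_that("fibre-colocalized intensity recovers painted stain levels", {
  sf <- single_fibre_image(width = 4, amplitude = 100)
  cell <- matrix(TRUE, 96, 96)
  maps <- segment_fibres(sf$img, cell, edge_erode = 0)
  # stain uniform on fibre pixels, explicit zero background
  stain <- matrix(0, 96, 96)
  stain[maps$fibre_mask] <- 63
  expect_equal(fibre_colocalized_intensity(stain, maps$fibre_mask,
                                           background = 0), 63)
  expect_equal(fibre_colocalized_intensity(matrix(0, 96, 96),
                                           maps$fibre_mask, background = 0), 0)
  # painted on-fibre level s over cytosol level b, background estimated
  cellm <- ellipse_mask(c(96, 96), 44, 42)
  st <- simulate_protein_stain(cellm, fibre_mask = maps$fibre_mask & cellm,
                               cytosol_level = 30, fibre_level = 90,
                               background = 10)
  got <- fibre_colocalized_intensity(st, maps$fibre_mask & cellm,
                                     background = 30)
  expect_equal(got, 90, tolerance = 0.03)
  # monotone in the painted level
  got2 <- fibre_colocalized_intensity(
    simulate_protein_stain(cellm, fibre_mask = maps$fibre_mask & cellm,
                           cytosol_level = 30, fibre_level = 120),
    maps$fibre_mask & cellm, background = 30)
  expect_gt(got2, got)
  # empty fibre mask -> missing, not zero
  expect_true(is.na(fibre_colocalized_intensity(st, cellm & FALSE,
                                                background = 0)))
})

test_that("nucleus descriptors match moment oracles on known shapes", {
  # 20 x 10 solid ellipse: axis ratio about 2
  nuc <- ellipse_mask(c(96, 96), 20, 10)
  nd <- nucleus_descriptors(matrix(1, 96, 96), nuc, pixel_size = 1)
  expect_equal(nd$axis_ratio, 2, tolerance = 0.05)
  # r = 10 disk: area near pi * 100
  disk <- ellipse_mask(c(64, 64), 10, 10)
  nd2 <- nucleus_descriptors(matrix(1, 64, 64), disk, pixel_size = 1)
  expect_equal(nd2$area, pi * 100, tolerance = 0.03)
  # rotation by 90 degrees preserves area exactly
  rot <- t(nuc)[, 96:1]
  nd3 <- nucleus_descriptors(matrix(1, 96, 96), rot, pixel_size = 1)
  expect_identical(nd3$area, nd$area)
  expect_error(nucleus_descriptors(matrix(1, 8, 8), matrix(FALSE, 8, 8), 1),
               "empty")
})
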