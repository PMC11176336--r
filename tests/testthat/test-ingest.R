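# Label-mask extraction, filtering, compartments, rescaling.

test_that("median intensity and record count come straight from the mask", {
  mask <- matrix(0L, 4, 6)
  mask[2, 1:5] <- 1L                       # one 5-pixel nucleus
  chan <- matrix(0, 4, 6)
  chan[2, 1:5] <- c(1, 2, 3, 4, 100)
  tab <- extract_nucleus_table(mask, list(ch = chan), pixel_size = 1)
  expect_equal(nrow(tab), 1)
  expect_equal(tab$intensity_ch, 3)
  mask[4, 1:2] <- 2L
  chan[4, 1:2] <- 7
  tab2 <- extract_nucleus_table(mask, list(ch = chan), pixel_size = 1)
  expect_equal(nrow(tab2), 2)
  expect_equal(tab2$nucleus_id, c(1L, 2L))
  expect_error(extract_nucleus_table(matrix(0L, 3, 3), list(), 1),
               "no labels")
  expect_error(
    extract_nucleus_table(mask, list(ch = matrix(0, 2, 2)), 1),
    "dimensions")
})

test_that("render -> extract round trip recovers the generator's truth", {
  cfg <- synthetic_config(n_epi = 12, n_ve = 40, seed = 5)
  sl <- generate_slice(cfg)
  img <- render_slice(sl, cfg)
  ext <- extract_nucleus_table(img$label_mask, img$channels, img$pixel_size)
  expect_equal(nrow(ext), nrow(sl$nuclei))
  m <- match(ext$nucleus_id, sl$nuclei$nucleus_id)
  dx <- ext$x_um + img$origin_um[1] - sl$nuclei$x_um[m]
  dy <- ext$y_um + img$origin_um[2] - sl$nuclei$y_um[m]
  expect_lt(sqrt(mean(dx^2 + dy^2)) / img$pixel_size, 1)   # < 1 px RMS
  for (ch in names(img$channels)) {
    truth <- sl$nuclei[[paste0("intensity_", ch)]][m]
    got <- ext[[paste0("intensity_", ch)]]
    expect_lt(max(abs(got - truth) / pmax(truth, 1e-9)), 0.1)
  }
  # a rendered disc is maximally circular up to rasterization
  expect_true(all(ext$circularity >= 0.9))
  expect_true(all(ext$circularity <= 1.1))
  # area conservation: total area equals pixel count times pixel area
  expect_equal(sum(ext$area_um2),
               sum(img$label_mask > 0) * img$pixel_size^2)
})

test_that("filters apply thresholds directly and are idempotent", {
  tab <- make_table(1:3, 1:3, 1:3)
  tab$area_um2 <- c(10, 60, 600)
  out <- filter_nuclei(tab, 50, 500, 0.5)
  expect_equal(out$area_um2, 60)
  expect_equal(attr(out, "removed"),
               list(area_low = 1L, area_high = 1L, circularity = 0L))
  # a perfect disc never fails the circularity criterion
  disc <- make_table(0, 0, 1)
  disc$circularity <- 1
  expect_equal(nrow(filter_nuclei(disc, 40, 400, 1)), 1)
  # idempotence
  once <- filter_nuclei(tab, 50, 500, 0.5)
  twice <- filter_nuclei(once, 50, 500, 0.5)
  expect_equal(once$nucleus_id, twice$nucleus_id)
})

test_that("an engineered fixture with 7 outliers keeps exactly 93 nuclei", {
  set.seed(20)
  tab <- make_table(runif(100), runif(100), runif(100))
  tab$area_um2 <- runif(100, 60, 300)
  tab$circularity <- runif(100, 0.7, 0.98)
  tab$area_um2[c(3, 17, 58)] <- c(5, 12, 30)       # too small
  tab$area_um2[c(41, 77)] <- c(800, 1200)          # too large
  tab$circularity[c(62, 90)] <- c(0.1, 0.4)        # not round
  out <- filter_nuclei(tab, 40, 400, 0.5)
  expect_equal(nrow(out), 93)
  expect_equal(attr(out, "removed"),
               list(area_low = 3L, area_high = 2L, circularity = 2L))
})

test_that("compartment assignment follows centroid containment", {
  masks <- compartment_masks(circle_polygon(40), circle_polygon(90))
  tab <- make_table(c(0, 60, 120), c(0, 0, 0), c(1, 1, 1))
  out <- assign_compartments(tab, masks)
  expect_equal(out$compartment, c("Epi", "VE", "excluded"))
  expect_error(
    compartment_masks(rbind(c(0, 0), c(2, 2), c(2, 0), c(0, 2)),
                      circle_polygon(90)),
    "self-intersecting")
  expect_error(compartment_masks(circle_polygon(90), circle_polygon(40)),
               "inside")
})

test_that("circular masks at the generator radii recover every synthetic
           compartment and assignment ignores row order", {
  sl <- generate_slice(synthetic_config(seed = 12))
  masks <- compartment_masks(circle_polygon(45, n = 720),
                             circle_polygon(100, n = 720))
  blank <- sl$nuclei
  blank$compartment <- NA_character_
  out <- assign_compartments(blank, masks)
  expect_equal(out$compartment, sl$nuclei$compartment)
  shuffled <- blank[sample(nrow(blank)), ]
  out2 <- assign_compartments(shuffled, masks)
  m <- match(out$nucleus_id, out2$nucleus_id)
  expect_equal(out$compartment, out2$compartment[m])
})

test_that("rescaling maps the per-slice maximum to exactly 1", {
  tab <- make_table(1:3, 1:3, c(10, 20, 40))
  out <- rescale_intensities(tab)
  expect_equal(out$rescaled_ch, c(0.25, 0.5, 1.0))
  flat <- make_table(1:3, 1:3, c(5, 5, 5))
  expect_equal(rescale_intensities(flat)$rescaled_ch, c(1, 1, 1))
})

test_that("rescaling scope is per slice; zero channels warn and zero out;
           rank order is preserved", {
  two <- rbind(make_table(1:3, 1:3, c(10, 20, 40), slice_id = "s1"),
               make_table(1:3, 1:3, c(1, 2, 8), slice_id = "s2"))
  out <- rescale_intensities(two)
  expect_equal(out$rescaled_ch[out$slice_id == "s1"], c(0.25, 0.5, 1))
  expect_equal(out$rescaled_ch[out$slice_id == "s2"], c(0.125, 0.25, 1))
  agg <- rescale_intensities(two, scope = "aggregate")
  expect_equal(max(agg$rescaled_ch), 1)
  expect_equal(sum(agg$rescaled_ch == 1), 1)
  dark <- make_table(1:3, 1:3, c(0, 0, 0))
  expect_warning(dz <- rescale_intensities(dark), "zero maximum")
  expect_equal(dz$rescaled_ch, c(0, 0, 0))
  set.seed(30)
  rnd <- make_table(1:20, 1:20, runif(20, 1, 100))
  rs <- rescale_intensities(rnd)
  expect_equal(rank(rs$rescaled_ch), rank(rnd$intensity_ch))
})

test_that("nucleus tables survive a write/read round trip", {
  sl <- generate_slice(synthetic_config(n_epi = 5, n_ve = 10, seed = 3))
  path <- tempfile(fileext = ".tsv")
  write_nucleus_table(sl$nuclei, path)
  back <- read_nucleus_table(path)
  expect_equal(back$x_um, sl$nuclei$x_um)
  expect_equal(back$intensity_cer1, sl$nuclei$intensity_cer1)
})

test_that("rendered TIFFs read back as the same mask", {
  cfg <- synthetic_config(n_epi = 4, n_ve = 8, r_ring = 25, r_out = 45,
                          seed = 6)
  sl <- generate_slice(cfg)
  img <- render_slice(sl, cfg)
  dir <- tempfile()
  paths <- write_rendered_slice(img, dir)
  mask <- read_image(paths[["label_mask"]], as_labels = TRUE)
  expect_identical(mask, img$label_mask)
})
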