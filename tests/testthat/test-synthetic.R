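# Synthetic slice and clonal-culture generators.

test_that("generation is deterministic under a fixed seed", {
  cfg <- synthetic_config(seed = 7)
  a <- generate_slice(cfg)
  b <- generate_slice(cfg)
  expect_identical(a$nuclei, b$nuclei)
  expect_identical(a$truth$channels, b$truth$channels)
  c <- generate_slice(synthetic_config(seed = 8))
  expect_false(identical(a$nuclei, c$nuclei))
})

test_that("compartment geometry is respected on every seed", {
  for (seed in 1:5) {
    sl <- generate_slice(synthetic_config(seed = seed))
    r <- sqrt(sl$nuclei$x_um^2 + sl$nuclei$y_um^2)
    epi <- sl$nuclei$compartment == "Epi"
    expect_true(all(r[epi] < 45))
    expect_true(all(r[!epi] >= 45 & r[!epi] <= 100))
    # minimum pairwise spacing of one nucleus diameter
    d <- stats::dist(cbind(sl$nuclei$x_um, sl$nuclei$y_um))
    expect_gte(min(d), 8)
  }
})

test_that("kappa = 0 channels are unpolarized in truth and their intensity
           carries no angular signal", {
  cfg <- synthetic_config(
    channels = list(channel_spec("flat", "VE", kappa = 0),
                    channel_spec("flat2", "Epi", kappa = 0)),
    seed = 3)
  sl <- generate_slice(cfg)
  expect_false(any(sl$truth$channels$polarized))
  # with kappa = 0 the mean intensity is position-independent: correlation
  # between intensity and angular position should be indistinguishable
  # from noise across seeds
  cors <- vapply(1:20, function(s) {
    sl <- generate_slice(synthetic_config(
      channels = list(channel_spec("flat", "VE", kappa = 0)), seed = s))
    ve <- sl$nuclei[sl$nuclei$compartment == "VE", ]
    cor(ve$intensity_flat, cos(atan2(ve$y_um, ve$x_um)))
  }, 0)
  expect_lt(abs(mean(cors)), 3 / sqrt(20 * 150))
})

test_that("mean polarization magnitude is non-decreasing in kappa", {
  # paired across kappa: replicate i reuses the same seed at every kappa so
  # geometry and noise are common random numbers
  n_rep <- 40
  mean_p <- vapply(c(0, 0.5, 1, 2, 4), function(kappa) {
    mean(vapply(seq_len(n_rep), function(i) {
      sl <- generate_slice(calibration_config(kappa, derive_seed(500, i)))
      tab <- rescale_intensities(sl$nuclei)
      ve <- tab[tab$compartment == "VE", ]
      polarization_vector(cbind(ve$x_um, ve$y_um), ve$rescaled_cer1)$p
    }, 0))
  }, 0)
  expect_true(all(diff(mean_p) > 0))
})

test_that("infeasible packings fail loudly instead of overlapping", {
  cfg <- synthetic_config(n_epi = 500, n_ve = 0, r_ring = 20, r_out = 30,
                          seed = 1)
  expect_error(generate_slice(cfg), "infeasible packing")
})

test_that("nested domains share the angle with different concentrations", {
  diff_deg <- function(a, b) min(abs(a - b), 360 - abs(a - b))
  p_core <- p_broad <- numeric(10)
  for (i in 1:10) {
    cfg <- synthetic_config(
      channels = list(channel_spec("core", "VE", theta0 = 45, kappa = 4),
                      channel_spec("broad", "VE", theta0 = 45, kappa = 1)),
      seed = derive_seed(900, i))
    sl <- generate_slice(cfg)
    tab <- rescale_intensities(sl$nuclei)
    ve <- tab[tab$compartment == "VE", ]
    pos <- cbind(ve$x_um, ve$y_um)
    core <- polarization_vector(pos, ve$rescaled_core)
    broad <- polarization_vector(pos, ve$rescaled_broad)
    expect_lt(diff_deg(domain_angle(core), 45), 30)
    expect_lt(diff_deg(domain_angle(broad), 45), 45)
    p_core[i] <- core$p
    p_broad[i] <- broad$p
  }
  # the tighter domain polarizes more strongly on average
  expect_gt(mean(p_core), mean(p_broad))
})

test_that("rendered slices conserve nucleus count and label identity", {
  cfg <- synthetic_config(n_epi = 3, n_ve = 0, r_ring = 30, r_out = 40,
                          channels = list(channel_spec("ch", "Epi")),
                          seed = 2)
  sl <- generate_slice(cfg)
  img <- render_slice(sl, cfg)
  labs <- sort(unique(img$label_mask[img$label_mask > 0]))
  expect_equal(labs, sl$nuclei$nucleus_id)
  expect_error(render_slice(sl, cfg, fov_um = 50), "too small")
})

test_that("clonal cultures: regimes, degenerate nest sizes, errors", {
  labels <- c("A", "B", "C")
  cc <- generate_clonal_culture(150, labels, "clonal",
                                list(n_nests = 8, nest_size = 5), seed = 4)
  sc <- clonality_score(cc$truth$nests, cc$nuclei)
  expect_equal(sc$summary$monoclonal_fraction, 1)
  # determinism
  cc2 <- generate_clonal_culture(150, labels, "clonal",
                                 list(n_nests = 8, nest_size = 5), seed = 4)
  expect_identical(cc$nuclei, cc2$nuclei)
  # nest size 1 is monoclonal under both regimes
  for (regime in c("clonal", "signaling")) {
    c1 <- generate_clonal_culture(60, labels, regime,
                                  list(n_nests = 6, nest_size = 1), seed = 5)
    s1 <- clonality_score(c1$truth$nests, c1$nuclei)
    expect_equal(s1$summary$monoclonal_fraction, 1)
  }
  expect_error(
    generate_clonal_culture(10, labels, "clonal",
                            list(n_nests = 4, nest_size = 5), seed = 1),
    "exceed")
})

test_that("nest members are spatially compact and marker-bright", {
  cc <- generate_clonal_culture(150, c("A", "B"), "signaling",
                                list(n_nests = 10, nest_size = 5), seed = 6)
  tab <- rescale_intensities(cc$nuclei)
  in_nest <- cc$truth$marker_positive
  expect_gte(mean(tab$rescaled_marker[in_nest] >= 0.3), 0.95)
  expect_lt(mean(tab$rescaled_marker[!in_nest] >= 0.3), 0.05)
  # members lie within the generating radius of their nest centroid
  for (nid in unique(cc$truth$nests$nest_id)) {
    ids <- cc$truth$nests$nucleus_id[cc$truth$nests$nest_id == nid]
    pos <- cbind(tab$x_um[ids], tab$y_um[ids])
    d <- stats::dist(pos)
    expect_lte(max(d), 2 * cc$truth$nest_params$nest_radius)
  }
})
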