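# Polarization vector, radius of gyration, domain angle.

test_that("radius of gyration matches closed forms and scales linearly", {
  square <- rbind(c(0, 0), c(1, 0), c(0, 1), c(1, 1))
  expect_equal(radius_of_gyration(square), sqrt(0.5))
  expect_equal(radius_of_gyration(2 * square), sqrt(2))
  expect_error(radius_of_gyration(rbind(c(0, 0))), "at least 2")
})

test_that("radius of gyration agrees with naive summation on random points", {
  set.seed(42)
  for (rep in 1:5) {
    pos <- matrix(rnorm(100, sd = 30), 50, 2)
    expect_equal(radius_of_gyration(pos), oracle_rgyr(pos),
                 tolerance = 1e-12)
  }
})

test_that("uniform weights give an exactly zero polarization vector", {
  set.seed(1)
  pos <- matrix(runif(40, -50, 50), 20, 2)
  pv <- polarization_vector(pos, rep(3.7, 20))
  expect_equal(pv$raw_vector, c(0, 0))
  expect_equal(pv$p, 0)
})

test_that("the hand-worked 4-nucleus example is reproduced exactly", {
  pos <- rbind(c(0, 0), c(2, 0), c(0, 2), c(2, 2))
  w <- c(1, 1, 1, 3)
  # hand summation: centroid (1,1); sum w*(r-c) = (2,2); P = (2,2)/6
  pv1 <- polarization_vector(pos, w, norm_exponent = 1)
  expect_equal(pv1$raw_vector, c(1 / 3, 1 / 3))
  expect_equal(pv1$magnitude, sqrt(2) / 3)
  expect_equal(pv1$r_gyr, sqrt(2))
  expect_equal(pv1$p, 1 / 3)
  pv2 <- polarization_vector(pos, w, norm_exponent = 2)
  expect_equal(pv2$p, sqrt(2) / 3 / 2)
  # and the independent naive-loop oracle agrees
  o <- oracle_polarization(pos, w)
  expect_equal(pv1$raw_vector, o$raw)
  expect_equal(pv1$p, o$p)
})

test_that("all weight on one nucleus points from the centroid to it", {
  pos <- rbind(c(0, 0), c(4, 0), c(0, 4), c(4, 4))
  w <- c(0, 0, 0, 5)
  pv <- polarization_vector(pos, w)
  expect_equal(pv$raw_vector, c(2, 2))
  expect_equal(pv$p, sqrt(8) / pv$r_gyr)
})

test_that("vectorized implementation matches the oracle to 1e-12", {
  set.seed(7)
  for (rep in 1:10) {
    n <- sample(5:40, 1)
    pos <- matrix(rnorm(2 * n, sd = 20), n, 2)
    w <- runif(n)
    for (e in c(1, 2)) {
      pv <- polarization_vector(pos, w, e)
      o <- oracle_polarization(pos, w, e)
      expect_equal(pv$raw_vector, o$raw, tolerance = 1e-12)
      expect_equal(pv$p, o$p, tolerance = 1e-12)
    }
  }
})

test_that("p is translation invariant, rotation equivariant, and obeys the
           scale law for both exponents", {
  set.seed(11)
  for (rep in 1:5) {
    pos <- matrix(rnorm(30, sd = 15), 15, 2)
    w <- runif(15)
    pv <- polarization_vector(pos, w)
    shifted <- polarization_vector(sweep(pos, 2, c(13.7, -8.2), `+`), w)
    expect_equal(shifted$raw_vector, pv$raw_vector, tolerance = 1e-10)
    expect_equal(shifted$p, pv$p, tolerance = 1e-10)
    rotated <- polarization_vector(rotate2d(pos, 63), w)
    expect_equal(rotated$p, pv$p, tolerance = 1e-10)
    expect_equal(rotated$raw_vector,
                 as.numeric(rotate2d(rbind(pv$raw_vector), 63)),
                 tolerance = 1e-10)
    s <- 2.5
    expect_equal(polarization_vector(s * pos, w, 1)$p, pv$p,
                 tolerance = 1e-10)
    pv2 <- polarization_vector(pos, w, 2)
    expect_equal(polarization_vector(s * pos, w, 2)$p, pv2$p / s,
                 tolerance = 1e-10)
  }
})

test_that("p under exponent 1 is bounded by the farthest-nucleus ratio", {
  set.seed(3)
  for (rep in 1:20) {
    n <- sample(3:30, 1)
    pos <- matrix(rnorm(2 * n, sd = 10), n, 2)
    w <- runif(n)
    pv <- polarization_vector(pos, w)
    centered <- sweep(pos, 2, colMeans(pos))
    bound <- max(sqrt(rowSums(centered^2))) / pv$r_gyr
    expect_lte(pv$p, bound + 1e-12)
  }
})

test_that("all-zero weights are flagged undefined, not reported as zero", {
  pos <- rbind(c(0, 0), c(1, 0), c(0, 1))
  expect_warning(pv <- polarization_vector(pos, c(0, 0, 0)), "zero")
  expect_false(pv$defined)
  expect_true(is.na(pv$p))
})

test_that("domain angle follows atan2 convention on [0, 360)", {
  pos <- rbind(c(0, 0), c(2, 0), c(0, 2), c(2, 2))
  east <- polarization_vector(pos, c(1, 3, 1, 3))   # pull towards +x
  expect_equal(domain_angle(east), 0)
  north <- polarization_vector(pos, c(1, 1, 3, 3))  # pull towards +y
  expect_equal(domain_angle(north), 90)
  zero <- polarization_vector(pos, rep(1, 4))
  expect_error(domain_angle(zero), "undefined")
})

test_that("compute_polarization restricts each channel to its compartment", {
  tab <- make_table(c(0, 1, 2, 10, 11, 12), c(0, 1, 0, 0, 1, 0),
                    c(1, 2, 3, 4, 5, 6),
                    compartment = rep(c("Epi", "VE"), each = 3))
  tab$intensity_other <- rev(tab$intensity_ch)
  tab <- rescale_intensities(tab)
  pol <- compute_polarization(tab, c(ch = "VE", other = "Epi"))
  expect_equal(nrow(pol), 2)
  expect_equal(pol$n_nuclei, c(3, 3))
  ve <- tab[tab$compartment == "VE", ]
  pv <- polarization_vector(cbind(ve$x_um, ve$y_um), ve$rescaled_ch)
  expect_equal(pol$p[pol$channel == "ch"], pv$p)
})
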