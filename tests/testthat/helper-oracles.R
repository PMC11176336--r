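# Independent brute-force oracles and fixture builders. These deliberately
# re-derive every quantity with naive loops so that agreement with the
# package's vectorized implementations is informative.

# Radius of gyration by explicit summation.
oracle_rgyr <- function(positions) {
  cx <- mean(positions[, 1]); cy <- mean(positions[, 2])
  s <- 0
  for (i in seq_len(nrow(positions))) {
    s <- s + (positions[i, 1] - cx)^2 + (positions[i, 2] - cy)^2
  }
  sqrt(s / nrow(positions))
}

# Normalized polarization magnitude by explicit summation.
oracle_polarization <- function(positions, weights, norm_exponent = 1) {
  cx <- mean(positions[, 1]); cy <- mean(positions[, 2])
  px <- 0; py <- 0
  for (i in seq_len(nrow(positions))) {
    px <- px + weights[i] * (positions[i, 1] - cx)
    py <- py + weights[i] * (positions[i, 2] - cy)
  }
  px <- px / sum(weights); py <- py / sum(weights)
  list(raw = c(px, py),
       p = sqrt(px^2 + py^2) / oracle_rgyr(positions)^norm_exponent)
}

# Exact permutation distribution of the normalized magnitude for small n:
# enumerate all n! weight orderings.
oracle_exact_null <- function(positions, weights, norm_exponent = 1) {
  perms <- all_permutations(length(weights))
  apply(perms, 1, function(idx) {
    oracle_polarization(positions, weights[idx], norm_exponent)$p
  })
}

all_permutations <- function(n) {
  if (n == 1) return(matrix(1, 1, 1))
  sub <- all_permutations(n - 1)
  do.call(rbind, lapply(seq_len(n), function(k) {
    rest <- seq_len(n)[-k]
    cbind(k, matrix(rest[sub], nrow(sub)))
  }))
}

# Connected components within a link distance by naive union-find.
oracle_components <- function(positions, link_distance) {
  n <- nrow(positions)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d <- sqrt(sum((positions[i, ] - positions[j, ])^2))
      if (d <= link_distance) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[ri] <- rj
      }
    }
  }
  vapply(seq_len(n), find, 1L)
}

# Partition of indices implied by a component labelling, as a canonical
# sorted list of sorted member vectors (label values themselves don't matter).
canonical_partition <- function(membership) {
  parts <- unname(split(seq_along(membership), membership))
  parts <- lapply(parts, sort)
  parts[order(vapply(parts, min, 1L))]
}

# Minimal nucleus table for unit tests.
make_table <- function(x, y, intensity, compartment = "VE",
                       aggregate_id = "a1", slice_id = "s1",
                       clonal_label = NA_character_) {
  n <- length(x)
  data.frame(aggregate_id = aggregate_id, slice_id = slice_id,
             nucleus_id = seq_len(n), x_um = x, y_um = y,
             area_um2 = rep(60, n), circularity = rep(0.9, n),
             compartment = compartment, clonal_label = clonal_label,
             intensity_ch = intensity, stringsAsFactors = FALSE)
}

rotate2d <- function(positions, phi_deg) {
  phi <- phi_deg * pi / 180
  R <- matrix(c(cos(phi), sin(phi), -sin(phi), cos(phi)), 2, 2)
  positions %*% t(R)
}

# One-channel synthetic slice config used across calibration tests: the
# VE-reporter geometry of the study conditions (n_ve = 150) at a given
# concentration and amplitude-to-noise ratio.
calibration_config <- function(kappa, seed, amplitude = 0.5, noise_sd = 0.1,
                               theta0 = 90) {
  synthetic_config(
    n_epi = 0, n_ve = 150,
    channels = list(channel_spec("cer1", "VE", baseline = 0.1,
                                 amplitude = amplitude, theta0 = theta0,
                                 kappa = kappa)),
    noise_sd = noise_sd, seed = seed)
}

# Generate -> rescale -> test one calibration slice; returns the polarized
# flag for the single VE channel.
classify_one_slice <- function(kappa, seed, n_perm = 100) {
  sl <- generate_slice(calibration_config(kappa, seed))
  tab <- rescale_intensities(sl$nuclei)
  ve <- tab[tab$compartment == "VE", ]
  pt <- permutation_test(cbind(ve$x_um, ve$y_um), ve$rescaled_cer1,
                         n_perm = n_perm, seed = derive_seed(seed, "null"))
  pt$polarized
}
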