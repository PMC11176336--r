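# belapol

Spatial polarization and clonality analysis for bilayered embryo-like
aggregates (BELAs): stem-cell structures with an epiblast-like (Epi) core
surrounded by a visceral-endoderm-like (VE) layer. When a subset of VE cells
differentiates into anterior visceral endoderm (AVE), its reporter
expression concentrates on one side of the structure; belapol answers, per
imaged Z-slice and compartment, *is this expression domain spatially
asymmetric, and how are two domains oriented relative to each other?* — and,
for 2D cultures with mixed clonal labels, *are marker-positive cell nests
monoclonal or mixed?*

It is aimed at quantitative imaging work on embryo-like aggregates and
similar organoids, consuming segmented-nucleus output (label masks from
e.g. StarDist, or ready-made per-nucleus tables) rather than raw microscopy.

## The statistic

For the nuclei of one compartment with centroids `r_i`, unweighted centroid
`c`, and per-nucleus rescaled median intensities `w_i` of a channel:

    P = sum_i w_i (r_i - c) / sum_i w_i          (polarization vector)
    R_gyr = sqrt(mean ||r_i - c||^2)             (radius of gyration)
    p = ||P|| / R_gyr^e                          (normalized magnitude, e = 1 default)

Uniform expression gives `P = (0, 0)` exactly. The null distribution of `p`
comes from shuffling the measured intensities across the fixed nucleus
positions; a domain is classified polarized when its observed `p` strictly
exceeds the shuffled magnitude in at least 95% of (by default) 100 draws,
ties counting against the call. The angle between two domains' vectors is
reported on [0, 180]°. Nests of marker-positive cells are fixed-radius
connected components, scored monoclonal when all members share one clonal
label; under a pure local-signaling model with `L` equiprobable labels and
nest size `m` the expected monoclonal fraction is `L^(1-m)`.

## Worked example

Generate a synthetic aggregate slice with a known AVE-like domain at 90° in
the VE and a mesoderm-like domain at 270° in the Epi, then quantify it:

```r
library(belapol)

cfg <- synthetic_config(seed = 7)           # 40 Epi + 150 VE nuclei
sl  <- generate_slice(cfg)
tab <- rescale_intensities(sl$nuclei)

pol <- compute_polarization(tab, c(cer1 = "VE", bra = "Epi"))
pol[, c("channel", "compartment", "n_nuclei", "r_gyr_um", "p",
        "domain_angle_deg")]
#>   channel compartment n_nuclei r_gyr_um     p domain_angle_deg
#> 1    cer1          VE      150     76.4 0.375             88.5
#> 2     bra         Epi       40     30.9 0.402            278.4
```

Both recovered domain angles sit within a few degrees of the generating
truth (90° and 270°), and the normalized magnitudes are far above the
shuffle null:

```r
ve <- tab[tab$compartment == "VE", ]
pt <- permutation_test(cbind(ve$x_um, ve$y_um), ve$rescaled_cer1,
                       n_perm = 100, seed = 42)
#> observed p = 0.375; null mean = 0.055;
#> exceeds 100% of null draws; polarized: TRUE

compute_angles(pol, "cer1", "bra")$angle_deg
#> [1] 170.1      # ground-truth offset: 180 deg
```

The same stages run end to end from a YAML config over many aggregates with
`run_pipeline()` (or the wrapper `inst/scripts/belapol-run.R`), writing
per-stage tables, a JSON manifest and a text summary; re-runs with the same
seed are byte-identical.

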