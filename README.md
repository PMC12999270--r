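# dropletkinetics

Quantitative image analysis for ribonucleoprotein condensate dynamics, with a
synthetic forward model that makes every measurement stage verifiable by
parameter recovery.

## The problem

Protein–RNA co-condensates (e.g. a DEAD-box helicase such as LAF-1 with a
structured RNA) are imaged as two-channel z-stack time-lapses. Over time the
RNA channel develops center-high radial gradients and its total intensity
decays, while the protein channel stays homogeneous; later, bright RNA puncta
appear that locally exclude protein. Quantifying this requires a chain of
careful measurements:

1. **Segmentation & tracking** — droplets are detected on the protein channel
   (Otsu threshold after Gaussian smoothing), the midplane of each droplet is
   the z-slice of maximal area, and midplane centroids are linked over time
   by nearest-neighbour assignment.
2. **Decay kinetics** — the RNA intensity at each droplet center (3×3 pixel
   neighbourhood of the centroid) is fit to a single exponential
   `I(t) = A e^{-t/τ} + B`. If RNA leaves through the droplet *surface*, the
   decay timescale scales with droplet radius, `τ = R/(3κ)` for surface
   departure velocity κ, and plotting intensity against `t/R` collapses
   curves of all sizes. Renormalized timescales below 10 min/µm are censored:
   such droplets have decayed to their plateau before observation starts.
3. **FRAP aging** — fluorescence recovery after photobleaching with an
   in-droplet reference: the spot/reference intensity ratio `I(t)` is
   rescaled as `N(t) = (I(t) − I(0)) / (I_i − I(0))`, so `N(0) = 0` exactly
   and global intensity drift cancels. `N(t)` is averaged across droplets in
   a field of view and fit to `M (1 − e^{-t/τ_rec})`; τ_rec plotted against
   the experiment's onset time reveals aging (slowing internal dynamics).
4. **Colocalization** — within the protein-defined droplet contour, the
   pixelwise normalized product of differences from the mean,
   `(A_ij − Ā)(B_ij − B̄)/(σ_A σ_B)`, whose mask mean equals the Pearson
   correlation; RNA puncta (a second, RNA-channel segmentation) overlap
   negative regions when they exclude protein.

Because raw microscope data for such experiments are rarely deposited, the
package ships a forward model: spherical droplets whose internal RNA obeys
radial diffusion with a Robin (surface-departure) boundary condition,
rendered through z-sectioning, Gaussian PSF blur and Poisson–Gaussian noise,
with optional bleach events and puncta. Every stage of the measurement
pipeline is tested by recovering the generator's known parameters.

## Worked example

```r
library(dropletkinetics)

# a 5-droplet scene, radii 1-4 um, kappa = 0.01 um/min, SNR 10
p  <- synthetic_params(D_rna = 10, kappa = 0.01, psf_sigma_um = 0.15,
                       rng_seed = 101, photon_scale = photon_scale_for_snr(10))
sc <- make_scene(5, field_size_um = 28, params = p, seed = 101,
                 radii = c(4, 3, 2, 1.5, 1), n_frames = 80)
movie  <- render_scene(sc)                  # noisy calibrated image stack
tracks <- track_droplets(movie$stack)       # tibble: one row per (track, frame)

fits <- fit_decays(tracks, renormalize = FALSE)
fits[, c("track_id", "R_um", "tau", "censored")]
#>   track_id  R_um    tau censored
#> 1        1 4.002 132.56    FALSE
#> 2        2 2.004  67.11    FALSE
#> 3        3 3.002 100.18    FALSE
#> 4        4 1.004  32.59    FALSE
#> 5        5 1.503  49.42    FALSE

collapse_quality(fits$fit)
#>   n cv_renormalized cv_raw tau_span slope_raw r_squared
#> 1 5         0.01229 0.5259    4.067      33.2         1
```

Raw timescales span ~4× across the radius range while `τ/R` is constant to
~1% — the signature of a surface-area-to-volume-limited process — and the
through-origin slope `τ/R = 33.2 min/µm` recovers `1/(3κ) = 33.3` within
half a percent, i.e. `κ̂ ≈ 0.0100 µm/min` against a ground truth of 0.01.

Plotting helpers: `plot_decay_curves(tracks, renormalize = TRUE)`,
`autoplot(fits$fit[[1]])`, `plot_aging(aging_series(...))`,
`plot_radial_profile(...)`; `tidy()`/`glance()` work on all fit objects.

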