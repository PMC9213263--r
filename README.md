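# mocolge

Motion-compensated reconstruction for free-breathing 3D Dixon LGE cardiac
MRI, with a built-in digital moving phantom.

## What it is for

Late gadolinium enhancement (LGE) imaging shows myocardial scar as bright
tissue against inversion-nulled myocardium. Free-breathing 3D dual-echo
acquisitions cover the whole heart at isotropic resolution, but respiratory
motion scatters each heartbeat's k-space lines across breathing positions.
`mocolge` implements and compares the two in-line reconstruction strategies
for such data:

* **TC** — translational correction: 2D image-navigator (iNAV) template
  tracking per heartbeat, k-space linear-phase correction toward the average
  breathing position, iterative SENSE (conjugate gradients on
  `E = M F S`, with sampling mask `M`, unitary centered FFT `F`, coil maps
  `S`):

  `x̂ = argmin_x Σ_c ‖ M F S_c x − y_c ‖²`

* **NRC** — combined translational + non-rigid correction: respiratory
  binning of the lines by foot–head navigator position, per-bin k-space
  re-centring, half-resolution bin-image reconstruction, histogram
  equalization and B-spline registration to the central bin, and a
  generalized motion-compensated encoding solved jointly over bins:

  `x̂ = argmin_x Σ_b Σ_c ‖ M_b F S_c W_b x − y_{b,c} ‖²`

  where `W_b` warps the reconstruction (average-breathing-position) anatomy
  into bin `b` by the estimated deformation field.

Both pipelines end with two-point Dixon water–fat separation
(`W = |IP + OP|/2`, `F = |IP − OP|/2`, optional smooth-phasor B0
demodulation) and FWHM scar-mass / contrast-ratio quantification.

Because raw patient data of this kind are not public, the package ships a
first-class synthetic-data module: a water/fat thorax–heart phantom with
subendocardial scar, pseudo-periodic breathing with a non-rigid component,
analytic multi-coil acquisition on a variable-density golden-step Cartesian
trajectory with spiral profile ordering (VD-CASPR, 3.3× undersampled), and
per-beat coronal dual-echo navigators.

## Worked example

Simulate one free-breathing scan at desk scale (64×64×32, 2 mm voxels,
8 coils, 3.3× VD-CASPR, 10 mm breathing with a non-rigid fraction of 0.5)
and reconstruct it with both pipelines:

```r
library(mocolge)
ex <- run_experiment(experiment_config(seed = 1))
str(ex$metrics[c("tc", "nrc")])
```

```
List of 2
 $ tc :List of 6
  ..$ rmse        : num 0.0319
  ..$ sharpness   : num 0.317
  ..$ cr_lge_myo  : num 5.12
  ..$ cr_blood_myo: num 7.19
  ..$ mass_g      : num 5.45
  ..$ rmse_truth  : num 0.0382
 $ nrc:List of 6
  ..$ rmse        : num 0.0318
  ..$ sharpness   : num 0.318
  ..$ cr_lge_myo  : num 5.15
  ..$ cr_blood_myo: num 7.23
  ..$ mass_g      : num 5.5
  ..$ rmse_truth  : num 0.0377
```

`rmse` is the masked image error against a motion-free reference
reconstruction (same trajectory, coils and noise, breathing frozen at the
average position); `sharpness` the normalized gradient magnitude across the
myocardium–blood border; `cr_*` the LGE-to-myocardium and blood-to-myocardium
contrast ratios over identical (copied) ROIs; `mass_g` the FWHM scar mass
(threshold = half of the maximal shell intensity; density 1.05 g/mL).
On this non-rigid scan NRC edges out TC on image error, border sharpness and
both contrast ratios; the uncorrected reconstruction (also in
`ex$metrics`) is far worse on every metric. The ground-truth scar mass is in
`ex$truth$scar_mass_g`.

Individual stages are exported if you want to build the pipeline yourself:
`build_phantom()`, `breathing_trace()`, `generate_vdcaspr()`,
`simulate_scan()`, `track_template()`, `assign_bins()`,
`phase_shift_correct()`, `reconstruct_bin_images()`, `register_nonrigid()`,
`itsense()` / `mc_itsense()`, `dixon_separate()`, `fwhm_mass()`,
`contrast_ratio()`. `save_container()` / `load_container()` round-trip the
raw-data bundle; `write_volume()` exports NIfTI. A thin command-line wrapper
lives in `inst/cli/mocolge.R`
(`Rscript mocolge.R simulate|traj|recon|dixon|experiment ...`).

See the vignette (`vignettes/motion-compensated-lge.Rmd`) for the model, all
tunable parameters, numerical choices and known limitations.

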