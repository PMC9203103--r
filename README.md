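# jmoct — computational refocusing for Jones-matrix PS-OCT

Jones-matrix polarization-sensitive optical coherence tomography (JM-OCT)
measures four complex tomograms per scan — the entries of the cumulative
measured Jones matrix `Jm(x,y,z) = Jout Js(x,y,z) Jin`. Its polarization
contrasts are phase-sensitive reconstructions: **local phase retardation**
`delta` (the wrapped phase difference of the eigenvalues of
`Jl = Jm(z2) Jm(z1)^-1`), **birefringence** `b = delta / (2 k0 Zd)`, and
**DOPU** (the norm of kernel-averaged Stokes vectors). Like all
high-resolution OCT, JM-OCT trades lateral resolution against depth of
focus — but because the contrasts are phase-based, the defocus cannot be
deconvolved channel by channel: all four channels must be refocused with one
phase-consistent operation, or the polarimetry breaks.

`jmoct` implements that pipeline for R:

* **Fresnel refocusing** — the phase-only filter
  `H⁻¹(fx,fy; zd) = exp[−iπ λc zd (fx²+fy²)]` applied to zero-padded en face
  planes of all four channels at once (`propagate_enface`,
  `refocus_volume`); 50-pixel zero padding removes the edge-aliasing
  artifact.
* **Automatic defocus estimation** — per-frame bulk (piston) phase
  correction, per-depth-block minimization of the image entropy
  `E = −Σ p ln p` of the refocused intensity (BFGS, 1 nm tolerance), and a
  linear depth fit `zd(z)` with depth-of-focus band exclusion and
  extrapolation (`bulk_phase_correct`, `estimate_defocus_profile`,
  `fit_defocus_linear`).
* **Polarimetric contrasts** — intensity composite, sliding-window
  birefringence with a reliability channel, noise-corrected DOPU on a 3×3
  kernel, and pseudo-colour composites (`birefringence_map`, `compute_dopu`,
  `pseudo_color_birefringence`, `pseudo_color_dopu`).
* **Synthetic JM-OCT phantoms** with exact ground truth — speckle from
  random scatterers, layered birefringent regions, depth-linear forward
  defocus, system matrices, additive complex noise, injectable bulk phase
  errors (`phantom_preset`, `simulate_jones_volume`,
  `inject_bulk_phase_error`).
* **Artifact quantification** — defocus sweeps of mean birefringence/DOPU,
  15×15-pixel region statistics, paired t-tests, and the four-condition
  (physically/computationally in-focus/defocused) experiment
  (`defocus_sweep`, `region_stats`, `four_condition_experiment`).
* **Container I/O and CLI** — a hierarchical directory container with
  bit-exact round trips (`write_volume` / `read_volume`), PNG/float-TIFF
  exports with JSON sidecars, and an `exec/jmoct` command-line front end
  (`simulate`, `refocus`, `contrast`, `sweep`, `fourway`).

See `vignettes/jmoct-methods.Rmd` for the models, parameter choices, and
known limitations.

## Worked example

Simulate a defocused particle-suspension phantom (512-A-line geometry scaled
to 128×128×64, focus mid-volume), estimate the defocus line automatically,
refocus, and reconstruct the contrasts:

```r
library(jmoct)

ph  <- phantom_preset("scattering", n_x = 128, n_y = 128, n_z = 64,
                      snr_db = 25, seed = 7)
vol <- simulate_jones_volume(ph)

prof <- estimate_defocus_profile(vol, block = 8)
prof <- fit_defocus_linear(prof, vol$geometry)
cat(sprintf("fitted defocus line: zd(z) = %.4f z %+.1f um (R^2 = %.5f)\n",
            prof$slope, prof$intercept, prof$r_squared))
cat(sprintf("ground truth:        zd(z) = %.4f z %+.1f um\n",
            1, -ph$focus_depth))

refocused <- refocus_volume(vol, prof)
bm <- birefringence_map(refocused, Zd_pixels = 8)
du <- compute_dopu(jones_to_stokes(refocused))

I <- intensity_composite(refocused)[seq_len(56), , ]
bright <- bm$valid & I > refocused$noise_floor * 10
cat(sprintf("birefringence window: %.2f um; median b over bright pixels = %.2e (true 0)\n",
            bm$Zd, median(bm$b[bright])))
cat(sprintf("median DOPU over bright pixels: %.3f\n",
            median(du$dopu[seq_len(56), , ][bright], na.rm = TRUE)))
```

Output:

```
fitted defocus line: zd(z) = 0.9974 z -227.5 um (R^2 = 1.00000)
ground truth:        zd(z) = 1.0000 z -228.1 um
birefringence window: 57.92 um; median b over bright pixels = 5.29e-04 (true 0)
median DOPU over bright pixels: 1.000
```

Reading the numbers: the entropy-minimizing estimator recovers the
simulator's defocus line (slope 1, focus at 228 µm) to 0.3%; the
birefringence window is 8 depth pixels × 7.24 µm = 57.92 µm; on this
non-birefringent phantom the masked median birefringence stays at the
noise-determined level (~5×10⁻⁴, well below tissue-like values of 10⁻³–10⁻²)
and DOPU is 1, as expected for a polarization-preserving sample.

The same pipeline from a shell:

```sh
exec/jmoct simulate --preset scattering --n-x 128 --n-y 128 --n-z 64 \
    --seed 7 --out volume.jmvol
exec/jmoct refocus --input volume.jmvol --out refocused.jmvol --block 8
exec/jmoct contrast --input refocused.jmvol --depth 8 --out-prefix maps
exec/jmoct sweep --input refocused.jmvol --depth 8 --out sweep.csv
```

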