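# shearTFM

Traction force microscopy (TFM) for cells under an externally applied
shear force.

## The problem

In standard TFM an adherent cell is mechanically isolated: the vector sum
of its traction forces vanishes, and the traction field can be
reconstructed per spatial-frequency mode with Fourier Transform Traction
Cytometry (FTTC). When a calibrated microneedle shears the cell, the
force balance acquires a **force monopole**: the tractions must sum to
the external needle force. The Boussinesq Green's function diverges at
zero wavevector, so FTTC cannot reconstruct this monopole mode, and
Tikhonov regularization — required by the usual inverse methods —
systematically underestimates the absolute force magnitudes that the
comparison with the needle force needs.

`shearTFM` implements a real-space **circular-patch method** that stays
well posed in the presence of a monopole. Each focal-adhesion patch is a
disc of uniform traction `q`; the surface displacement it produces on an
elastic half-space (Young's modulus `E`, Poisson ratio `nu`) is the disc
integral of the tangential Boussinesq tensor

    G_ij(r) = (1 + nu) / (pi E |r|) [ (1 - nu) delta_ij + nu r_i r_j / r^2 ],

which is finite everywhere (at the patch center it reduces to
`u = q a (1+nu)(2-nu) / E` for radius `a`). Per-patch force vectors are
fitted to the measured substrate displacement field by **unregularized
linear least squares**, so absolute magnitudes are unbiased and the net
traction can be compared directly with the needle force.

Around this core the package provides:

- **PIV** displacement extraction from fluorescent bead images (64-px
  windows, 50% overlap, FFT cross-correlation, Gaussian subpixel peak
  fit, SNR >= 1.5 peak-ratio filter, normalized median test at 2.0);
- **FTTC** with 0th-order Tikhonov regularization and exact per-mode
  generalized cross-validation (GCV), used at t = 0 (zero monopole) to
  cross-validate the patch method;
- **needle calibration**: the spring constant of the microneedle from
  shearing a PDMS micropillar (cantilever stiffness `3EI/L^3`, optional
  Timoshenko shear correction), and the per-frame shear force
  `F = k * bending`;
- **force moments**: monopole, major/minor dipole eigen-moments and
  torque about the magnitude-weighted contractile center;
- a **synthetic-data generator** that renders bead images deformed by
  known traction fields (ramped monopole, rupture events, pillar
  calibration tracks) with exact ground-truth force accounting.

## Worked example

Simulate a needle-shearing experiment (9 adhesion patches on 16.5 kPa
polyacrylamide, external force ramping to 100 nN along +y at 0.85 fps)
and reconstruct it from the bead images alone:

```r
library(shearTFM)

substrate <- elastic_substrate(16.5e3, 0.5)       # Pa, Poisson ratio
scen <- default_scenario("colinear", n_frames = 6)
spec <- bead_field_spec(n_beads = 2200, image_shape = c(384, 384), seed = 1)
sim  <- simulate_shear_experiment(scen, spec, substrate)

sets <- reconstruct_time_series(sim$images, sim$reference, sim$windows,
                                piv_settings(), substrate, frame_rate = 0.85)
tab <- force_series_table(sets)
subset(tab, frame == 5, select = c(time_s, patch_id, Fy_nN, net_mag_nN))
#>    time_s patch_id      Fy_nN net_mag_nN
#>  5.882353        1 21.6372405   89.21749
#>  5.882353        2 -2.6266719   89.21749
#>  ...
#>  5.882353        9  8.4689271   89.21749
```

The per-patch `Fy_nN` column shows how the cell distributes the pull:
the patch under the needle and the tension-side patches are loaded, the
compression-side patches are not. The net traction magnitude tracks the
needle force computed from the needle track:

```r
nb <- needle_bending_series(sim$needle_track, sim$needle_speed, c(0, 1),
                            spec$pixel_size)
nf <- needle_force_series(nb, sim$k_needle)
#> frame 5: needle force 100.0 nN, net traction 89.2 nN
```

Force moments quantify the transition from dipole- to
monopole-dominated force balance:

```r
moments_table(moments_time_series(sets))[c(1, 6), ]
#>  time_s M0_nN Dmajor_nNum Dminor_nNum torque_nNum
#>    0.00  1.37     -538.24     -148.09       10.36
#>    5.88 89.22     -283.52      -86.64      -17.61
```

A command-line front end wraps the same functions:

```sh
Rscript inst/cli/tfm.R simulate --out data/run1 --type colinear --seed 1
Rscript inst/cli/tfm.R reconstruct --config config.yaml
```

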