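# nearedge

Structure-to-spectrum machine learning for K-edge X-ray absorption
near-edge structure (XANES).

The near-edge region of a K-edge absorption spectrum is shaped by multiple
scattering of the ejected photoelectron off the atoms around the absorption
site, so it encodes the local geometry — coordination numbers, bond
distances, bond angles. Going the other way (structure → spectrum) normally
requires multiple-scattering calculations that take hours per site.
`nearedge` is for spectroscopists and computational chemists who want a
fast surrogate instead: featurise the local environment around an absorber,
train a neural network on precomputed spectra once, then predict new
spectra instantly.

## What's inside

**Representations.** The local environment (element + Cartesian
coordinates, XYZ files with an `absorber=<i>` tag) is encoded either as

- a **sorted Coulomb matrix**: `M[I,I] = Z_I^2.4 / 2`,
  `M[I,J] = Z_I Z_J / |R_I − R_J|` over the `N` atoms nearest the absorber
  (default `N = 20`), rows/columns permuted to non-increasing row norm,
  upper triangle flattened to a length-`N(N+1)/2` vector (210 at `N = 20`);
  or
- a **radial distribution curve (RDC)**:
  `f(R) = Σ_{I<J} Z_I Z_J exp(−α (r_IJ − R)²)` over all pairs within a
  cutoff radius of the absorber (defaults `α = 10 Å⁻²`, cutoff 4.0 Å, 800
  grid points spanning twice the cutoff).

Both are invariant to rotations, translations, and atom ordering.

**Model.** A multilayer perceptron with hidden layers 1200 → 840 → 588 →
411 (30% shrink per layer), tanh activations, linear output, MSE cost,
ADAM (η = 3×10⁻⁴) over minibatches of 100 with 15% dropout — all
configurable, fully seeded, with training-set feature standardisation
stored in the model.

**Post-processing.** Predicted cross-sections are broadened with a
Lorentzian whose full width follows the energy-dependent arctangent model
`Γ(E) = Γi + Γf (1/2 + arctan[(π/3)(Γf/Ew)(e/Ec − Ec²/e²)]/π)`, `e = E −
Ef`, evaluated in closed form against the piecewise-linear spectrum.

**Evaluation.** Repeated K-fold cross-validation (default 5 folds × 5
repetitions), learning curves over in-sample size, peak-parity R² for peak
energies and intensities, centile ranking of per-sample errors, and
encoded-radius histograms for cluster populations.

**Synthetic data.** A seeded generator of random Fe-centred coordination
clusters plus a deterministic toy structure→spectrum map, so the entire
pipeline trains and tests offline. See the methods vignette
(`vignettes/methods.Rmd`) for the model details and its limits.

## Worked example

```r
library(nearedge)

## 400 synthetic clusters and their toy spectra on a 100-point grid
cfg <- synthetic_config(n_clusters = 400,
                        energy_grid = seq(0, 100, length.out = 100),
                        seed = 7)
ds <- make_dataset(cfg)

## charge-weighted RDC features on a 200-point grid
feats   <- featurise_batch(ds$clusters, "rdc",
                           rdc_config(grid = seq(0, 8, length.out = 200)))
targets <- spectra_matrix(ds$spectra)

## cross-validate a reduced-width funnel MLP (128 -> 89 -> 62 -> 43)
mcfg   <- mlp_config(input_dim = 200, output_dim = 100,
                     first_hidden = 128, seed = 1)
report <- kfold_evaluate(feats, targets$y, mcfg,
                         cv_config(k = 5, repetitions = 2, seed = 3),
                         epochs = 60)
report
#> <evaluation_report> 5-fold x 2 reps: out-of-sample MSE 0.0343225 +/- 0.00231

baseline <- mean(sweep(targets$y, 2, colMeans(targets$y))^2)
baseline / report$mean
#> [1] 2.287...
```

The report's `0.034` is the mean squared pointwise error between held-out
toy spectra and their predictions, averaged over the ten fold evaluations
(± one standard deviation across folds); the predict-the-mean baseline
(`0.079`) shows the model has learnt real structure→spectrum signal even
at this small sample size (the margin grows to >5× at 2000 samples — see
below). Broadening and peak extraction then work on single spectra:

```r
obs  <- arctan_convolve(spectrum(targets$energy, targets$y[1, ]),
                        conv_params(gamma_f = 5))
pred <- arctan_convolve(spectrum(targets$energy,
                                 report$predictions[[1]][1, ]),
                        conv_params(gamma_f = 5))
find_peaks(obs)
#>     energy intensity
#> 1 55.55556  1.045924
find_peaks(pred)
#>     energy intensity
#> 1 54.54545 0.6492449
```

The out-of-sample prediction for this sample places the broadened
resonance within one grid step (~1 eV) of the target; its intensity is
underestimated, which is typical at 400 training samples.

A command-line wrapper over the same functions is installed at
`inst/cli/nearedge` (subcommands `generate`, `featurise`, `train`,
`predict`, `convolve`, `evaluate`, `plot`).

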