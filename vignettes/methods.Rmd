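---
title: "Predicting K-edge near-edge spectra from local structure: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting K-edge near-edge spectra from local structure: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nearedge)
```

## The problem

The X-ray absorption near-edge structure (XANES) of a K-edge — the first
~50 eV above the excitation of a 1s core electron — is shaped by multiple
scattering of the photoelectron off the atoms surrounding the absorption
site. It therefore encodes coordination numbers, bond distances, and bond
angles of the local environment, but extracting a spectrum from a candidate
structure requires multiple-scattering calculations that can take hours per
site. `nearedge` implements the surrogate-model alternative: encode the
local environment around an absorbing atom as a fixed-length feature
vector, and train a multilayer perceptron (MLP) to map that vector directly
onto the discretised absorption cross-section. Once trained, predictions
are effectively instantaneous, which is what makes spectral analysis of
disordered or dynamically evolving systems tractable.

The package covers the full pipeline: structure I/O and local-environment
extraction, two featurisers, the MLP, an energy-dependent lifetime
broadening applied as post-processing, the evaluation protocol (repeated
K-fold cross-validation, learning curves, peak parity, centile ranking,
encoded-radius histograms), and a seeded synthetic data generator so that
every stage is trainable and testable offline.

## Representations of the local environment

Both featurisers operate on an absorber-centred cluster: element symbols
(as nuclear charges $Z$) plus Cartesian coordinates in Ångström, with one
site designated the absorber.

### Sorted Coulomb matrix (CM)

The Coulomb matrix of the $N$ sites nearest the absorber is

$$
M_{IJ} =
\begin{cases}
\tfrac{1}{2} Z_I^{2.4} & I = J \\
\dfrac{Z_I Z_J}{|R_I - R_J|} & I \neq J ,
\end{cases}
$$

with distances in Ångström by default (a Bohr switch is provided; it only
rescales the off-diagonal features). The rows and columns are permuted
simultaneously so that row $L_2$ norms are non-increasing, which makes the
representation invariant to atom indexing as well as to rotations and
translations; the upper triangle (diagonal included) is then flattened
row-wise into a vector of length $N(N+1)/2$ — 210 at the default $N = 20$.
Clusters with more than $N$ atoms are truncated to the $N$ nearest the
absorber; smaller clusters are zero-padded, and the zero rows sort to the
end automatically because their norm is zero.

Two conventions are deliberately pinned down because they affect
bit-reproducibility:

* the absorber is counted among the "nearest $N$" (it carries the dominant
  on-diagonal term $\tfrac12\,26^{2.4} \approx 1244$ for Fe), and
* ties — both equidistant atoms in the nearest-$N$ selection and equal row
  norms in the sort — are broken by original input order (stable sort), so
  symmetric geometries featurise deterministically.

### Radial distribution curve (RDC)

The RDC encodes the same environment as an intensity distribution over
interatomic distance,

$$
f_{\mathrm{RDC}}(R) = \sum_{I} \sum_{J > I} w_I\, w_J\,
  e^{-\alpha (r_{IJ} - R)^2},
$$

where the sum runs over *all* pairs among the sites within the cutoff
radius of the absorber (absorber included; the double sum carries no
absorber restriction), $w$ is a per-element weight (nuclear charge by
default, any scalar atomic property optionally), and $\alpha$ controls the
resolution: larger $\alpha$ sharpens peaks, and the full width at half
maximum of any single-pair peak is non-increasing in $\alpha$. Defaults are
$\alpha = 10\,\text{Å}^{-2}$ and a 4.0 Å cutoff. $\alpha$ is interpreted in
Å$^{-2}$; on a pm$^2$ scale the same number would collapse every kernel to
numerical zero, and the useful 0.5–200 range only makes sense in Å$^{-2}$.

The evaluation grid spans 0 to twice the cutoff (so every representable
pair distance fits) with 800 evenly spaced points by default. The grid is
fully configurable; 800 points at the default cutoff puts the downstream
network's parameter count near three million, matching the scale the
architecture was designed around. Cutoff radii quoted in pm in
configuration files are converted to Å on read.

## The network

The MLP is a funnel of four fully connected hidden layers: 1200 neurons in
the first, each subsequent layer 30% smaller than its predecessor with
floor rounding, i.e. 1200, 840, 588, 411. Hidden layers use the hyperbolic
tangent, which bounds activations in $(-1, 1)$; the output layer is linear,
because cross-sections are non-negative unbounded quantities that a
saturating output would clip. The cost is the mean squared error (MSE)
over samples and grid points, minimised by ADAM (learning rate
$3 \times 10^{-4}$, standard moment defaults $\beta_1 = 0.9$,
$\beta_2 = 0.999$, $\epsilon = 10^{-8}$) over shuffled minibatches of 100
samples, with 15% inverted dropout on the hidden layers during training
only. At the default RDC input (800) and spectrum output (300) dimensions
the model carries about $2.8 \times 10^6$ trainable parameters.

Choices the architecture description leaves open, fixed here:

* **Layer rounding.** Sizes shrink by `floor(prev * 0.70)`
  ($588 \times 0.7 = 411.6 \rightarrow 411$).
* **Initialisation.** Symmetric uniform fan-in,
  $U(-1/\sqrt{n_{\text{in}}}, 1/\sqrt{n_{\text{in}}})$, from the seeded
  generator; biases start at zero. The scheme is recorded in the model
  object.
* **Dropout placement.** Hidden layers only, never input or output, and
  never at prediction time — predictions are deterministic and
  repeat-stable.
* **Feature standardisation.** Each feature column is standardised to zero
  mean and unit variance using statistics estimated on the training set and
  stored in the model (`scale_features = TRUE` by default). Raw CM and RDC
  entries reach hundreds of charge-squared units; feeding them unscaled
  saturates the tanh first layer and stalls training long before
  convergence.
* **Epoch budget.** 500 epochs by default — the task is learnable within
  500 forward passes through the dataset — with an optional early-stopping
  `patience`.
* **Determinism.** The configuration seed drives initialisation, minibatch
  shuffling, and dropout masks through an isolated RNG scope; identical
  seeds give bit-identical weights and training histories, and the caller's
  RNG state is never touched.

The analytic backpropagation gradients are verified against central finite
differences in the test suite (toy network, relative agreement $10^{-5}$).

## Lifetime broadening

Computed (and predicted) cross-sections are unbroadened; to compare with
experiment they are convolved with a kernel whose full width depends on
energy through an arctangent switch-on,

$$
\Gamma(E) = \Gamma_i + \Gamma_f \left( \frac12 + \frac{1}{\pi}
  \arctan\!\left[ \frac{\pi}{3} \frac{\Gamma_f}{E_w}
  \left( \frac{e}{E_c} - \frac{E_c^2}{e^2} \right) \right] \right),
\qquad e = E - E_f ,
$$

where $\Gamma_i$ is the constant core-hole width, $\Gamma_f$ the
final-state width reached far above the edge, and $E_c$, $E_w$ the centre
and width of the switch-on. For $e \le 0$ the argument diverges to
$-\infty$ and $\Gamma$ takes its limiting value $\Gamma_i$ — this is also
how the $e \to 0$ singularity of $E_c^2/e^2$ is handled numerically.
$\Gamma$ is therefore bounded in $[\Gamma_i, \Gamma_i + \Gamma_f]$ and
non-decreasing above the edge.

The width formula does not fix the kernel shape. The implementation uses a
Lorentzian (the lifetime-broadening convention; a Gaussian switch is
provided), with the width evaluated at the *output* energy. Numerically:

* The input spectrum is treated as piecewise linear and integrated against
  the kernel in closed form per segment (arctan/log antiderivatives for the
  Lorentzian, error-function forms for the Gaussian). No quadrature error
  is introduced beyond the piecewise-linear model of the input, which is
  exactly the discretisation the spectra already live on; the test suite's
  independent dense-quadrature oracle converges to this implementation.
* Each kernel is normalised to unit area *over the spectrum's grid*. A
  Lorentzian's heavy tails hold several percent of its mass outside any
  practical energy window; truncated-kernel renormalisation restores unit
  mass so that interior spectral features keep their integrated intensity.
* Direct per-output-point evaluation is $O(n^2)$, which is negligible for
  spectra of a few hundred points and — unlike an FFT — exact for an
  energy-varying width.

Because the width varies with output energy, integrated intensity is
conserved only where $\Gamma$ varies slowly across one kernel width;
near the switch-on (within roughly $E_c$ of the edge) a spectral feature
can lose a few percent of its integral. The conservation-to-1% property
asserted in the tests therefore uses features sitting above the
arctangent turn-on, and the double-convolution guard plus the
uniform-grid requirement are enforced at the API level. The convolution is
strictly post-processing: training targets are never broadened.

Default parameters ($\Gamma_i = 1.25$, $\Gamma_f = 15$, $E_c = E_w = 30$
eV, $E_f = 0$ on a relative scale) are placeholders of a physically
plausible magnitude for a K-edge; every value is user-settable, and
analyses that need resolved peaks (e.g. the peak-parity statistics below)
should choose $\Gamma_f$ commensurate with the spectral linewidths.

## Evaluation protocol

* **Repeated K-fold cross-validation.** Five folds (an 80:20 split) with
  five independent re-partitions by default: $25$ fold evaluations, every
  sample out-of-sample exactly once per repetition, fold sizes differing by
  at most one. Performance is always reported on the held-out fold. The
  partition and each fold model's training are seeded, so a report is
  bit-reproducible.
* **Learning curves.** For each requested in-sample size a seeded
  subsample (without replacement, fresh per size; the full-size point uses
  the whole dataset) is cross-validated and the mean ± sd of the fold MSEs
  recorded.
* **Peak parity.** Peak extraction is not part of the underlying model and
  had to be defined: local maxima with topographic prominence at least 5%
  of the global maximum, on broadened spectra. Each target peak is greedily
  matched (in energy order) to the nearest unused estimated peak within a
  5 eV window; pooled pairs give $R^2$ for peak energy and peak intensity.
  $R^2$ is the squared Pearson correlation of the pooled pairs by default,
  with the identity-line variant $1 - SS_{\mathrm{res}}/SS_{\mathrm{tot}}$
  available; the choice and all thresholds are recorded in the result.
  With fewer than two pairs $R^2$ is reported as `NA`, never fabricated.
* **Centile ranking.** Per-sample out-of-sample MSEs are ranked ascending
  (stable under ties) and assigned `ceiling(100 * rank / n)`: the first
  centile is the best-predicted 1%, the hundredth the worst. The ranking
  is invariant under any strictly monotone transform of the scores.
* **Encoded-radius histograms.** For a cluster population, the
  distribution of (a) the radius to the $N$-th nearest atom — the largest
  radius an $N \times N$ CM encodes — and (b) the number of sites within a
  fixed radius — the CM dimension needed to encode it, absorber included
  (switchable). Both histograms are normalised to unit area and their
  modal bins reported.

## Synthetic data

The generator provides seeded, regenerable datasets with a known
structure-to-spectrum map so the pipeline can be exercised and its learning
behaviour measured without external structure libraries or
multiple-scattering codes.

**Clusters.** An Fe absorber sits at the origin; 8–30 sites are placed on
2–4 randomised coordination shells between 1.8 and 4.5 Å with 0.1 Å radial
jitter, rejecting any placement closer than 1.0 Å to an existing atom
(with a bounded redraw of the shell layout if a draw becomes too crowded
to finish). Shell placement, rather than uniform filling, is deliberate:
coordination-shell structure is exactly what the CM and RDC encode, and
the premise of the whole approach is that near-edge spectra are functions
of that local geometry. Neighbour elements are drawn from an O/F/S ligand
palette. Excluding Fe from the neighbour palette is a deliberate
identifiability choice: with the nuclear-charge-weighted RDC, a
ligand–ligand pair involving a second Fe would carry exactly the same
$26 \cdot Z$ weight signature as an absorber–ligand pair, making the toy
forward map below partially unrecoverable from the features and capping
what any model could learn.

**Toy forward model.** The spectrum of a cluster is a sum of Gaussian
lines contributed by its four nearest neighbours: the neighbour at
distance $d$ with charge $Z$ adds a line centred at $15 + 15d$ eV, of
height $Z/26$ and width $\sigma = 2 + 0.2d$ eV, on a 0–100 eV grid. The
map depends only on invariant geometry (so it is exactly
rotation/translation/permutation invariant), is smooth in the coordinates,
and has a closed form that tests can anchor on — scaling all bond lengths
by $s$ moves each line by exactly $15(s-1)d$ eV. It makes no claim of
physical XANES realism: there is no edge jump, no multiple-scattering
interference, no charge-state dependence, and no noise. Consequently,
passing end-to-end tests demonstrates that the pipeline's machinery —
featurisation, optimisation, evaluation — works and that the features
carry the geometric information the task needs; it says nothing about
attainable accuracy on real materials data.

## Problem sizes and numerical choices

The test suite and the acceptance script run the pipeline at reduced
dimensions chosen as a deliberate trade-off between statistical
meaningfulness and desk-scale runtimes: 2000 clusters, a 200-point RDC
grid, a 100-point energy grid, and a funnel entered at 256 neurons
(256 → 179 → 125 → 87 by the same 30% rule). At these sizes the default
pipeline reaches an out-of-sample MSE more than five times below the
predict-the-mean baseline within 150 of the 500 budgeted epochs, and the
cross-validated learning curve decreases from 100 to 2000 in-sample
spectra. The full-width architecture (1200 first hidden layer, ~2.8M
parameters) is exercised structurally (shapes, parameter count, gradient
correctness) rather than trained to convergence in the tests.

Other numerical conventions worth knowing:

* clusters with any pair of sites closer than 0.1 Å are rejected as
  corrupt input at construction time;
* coincident atoms inside a Coulomb matrix raise a singular-geometry
  error rather than producing infinities;
* a single-site environment yields an all-zero RDC, and `max1`
  normalisation of an all-zero spectrum is an error rather than a NaN;
* resampling is linear interpolation and refuses to extrapolate;
* batch featurisation isolates per-cluster failures (itemised in the
  result) and fails only if every cluster fails;
* all derived seeds stay within 32-bit integer range.

## Limitations

The package operates on pre-extracted finite clusters, not periodic
crystals; CIF/symmetry handling, site disorder, spectrum-to-structure
inversion, edge-shift/charge-state modelling, and the multiple-scattering
forward calculation itself are out of scope. The MSE scale of any reported
evaluation depends on the intensity normalisation of the training spectra,
which is configurable and recorded but has no single canonical choice;
comparisons between runs are only meaningful at matching normalisation.
Peak-extraction thresholds (prominence, matching window) are declared
defaults, not community standards, and materially affect parity statistics
under heavy broadening.
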