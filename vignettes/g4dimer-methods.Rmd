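---
title: "Modelling stacked G-quadruplex dimers: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling stacked G-quadruplex dimers: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(g4dimer)
```

## The system and the model

Guanine-rich telomeric DNA folds into G-quadruplex (G4) units, and a
50-nucleotide telomeric repeat carries two tandem units joined by a TTA
linker.  The two units can stack base-to-base at their interface or float
apart on the flexible linker, and small-molecule ligands shift this
equilibrium.  Solution SAXS sees the consequence directly — stacked dimers
are more compact — but an ensemble model is needed to turn a scattering
curve into a stacked fraction.

`g4dimer` implements an extremely coarse-grained representation of this
system.  Each G4 unit is a hard cylinder (radius $R_{HC}$, height $H$;
defaults 1.26 nm and 2.64 nm, the values that best reproduce experimental
profiles of telomeric dimers).  Two kinds of spherical interaction patches
decorate each cylinder:

* a **linker patch** of radius $R_0 = 0.53$ nm on the rim of one base.  The
  patch centers of the two cylinders of a dimer interact through an
  *infinite* square well of width $2R_0$: the pair may never separate
  beyond it.  This well *is* the whole linker model; no explicit polymer is
  simulated.
* a **stacking patch** of radius $R_1 = 0.265$ nm at the center of each
  base.  The facing pair interacts through a *finite* square well of width
  $2R_1$ and depth $u_0$.

All energies are expressed in units of $u_0$, so a single dimensionless
effective temperature $T^* = k_B T / u_0$ controls the stacking strength:
$T^* = 0$ freezes dimers in the stacked state, $T^* = \infty$ removes the
stacking bias entirely and the units stack only by geometric accident.

A dimer is **stacked** when the facing stacking patch centers are within
$2R_1$; the pair energy is then $-1$, otherwise $0$ (or $+\infty$ if the
hard constraints are violated).  The central observable is the stacked
fraction $p_{st}$ of an ensemble.

### Patch placement conventions

Two details are genuinely open in a patchy-cylinder description and were
fixed as follows.  First, each cylinder carries exactly one linker patch
and the junction involves a single linker pair and a single stacking pair:
cylinder A uses its $+$axis base, cylinder B its $-$axis base.  This gives
one well-defined junction per dimer; letting the well act on all four base
combinations would create spurious second junctions.  Second, the linker
patch sits at one discrete rim point, not on a ring, so the rotation of a
cylinder about its own axis (the azimuth) is a real degree of freedom,
sampled by the Monte Carlo moves and coupled to the partner through the
linker well.

## Monte Carlo sampling

Sampling is canonical Metropolis in $NVT^*$ over $N$ *independent* dimers:
only intra-dimer energetics exist.  The periodic box is bookkeeping — the
dilute experimental conditions justify ignoring inter-dimer interference,
and the default box keeps the cylinder volume fraction at 0.5%.  One sweep
attempts $2N$ single-cylinder moves, each a random translation (uniform in
a cube) or rotation (random axis, bounded angle) of one cylinder of one
dimer.  Moves violating a hard constraint are rejected outright; otherwise
acceptance is $\min(1, e^{-\Delta E / T^*})$, with dedicated code paths for
$T^* = 0$ (reject any increase) and $T^* = \infty$ (accept all feasible) to
avoid floating-point infinities.

Move amplitudes are tuned toward 30–50% acceptance during the first half of
thermalization and then frozen, so production sampling satisfies detailed
balance.  "Step" counting is in sweeps; rather than relying on a fixed step
budget, every run applies a drift test to the production energy trace
(total stacking energy, always $-$ the number of stacked dimers) and flags
non-equilibrated runs with a warning.

The overlap test for two solid finite cylinders is a GJK algorithm built on
the cylinder support function, covering all contact cases (lateral, cap,
rim).  Two numerical safeguards matter: the radial part of the support
direction is re-orthogonalized against the axis, because for directions
nearly parallel to the axis floating-point noise would otherwise be
amplified by $R/|d_r|$ into support points outside the body; and touching
configurations below the $10^{-10}$ nm tolerance are classified as
non-overlapping (they form a measure-zero set).  The test is validated in
the suite against a dense point-membership oracle over random pose pairs.

Two independent cross-checks anchor the sampler: at $T^* = \infty$ the
stacked fraction must match a direct rejection-sampling estimate of the
geometric probability of landing in the stacking well under the
linker-constrained uniform measure (`pst_geometric_oracle()`), and at
finite $T^*$ the stacked/unstacked odds must equal those geometric odds
amplified by $e^{1/T^*}$ — a Boltzmann/detailed-balance identity the test
suite verifies to within Monte-Carlo error.  That geometric probability is
small (about $6\times10^{-4}$ for the default geometry), which is why the
free dimer is mostly unstacked and ligand-induced stacking produces a
measurable compaction signal.

## From configurations to SAXS intensities

Every cylinder of every snapshot is replaced by $n_p$ points (default 100)
drawn uniformly from its volume, and the intensity is the Debye sum over
*intra-dimer* point pairs, averaged over dimers and snapshots:
$$ I(Q) = \frac{1}{n_d\,m^2}\sum_d \Big[ m + 2\sum_{i<j\in d}
   \frac{\sin(Q r_{ij})}{Q r_{ij}} \Big], \qquad m = 2 n_p, $$
normalized so $I(0) = 1$.  Cross-dimer terms are omitted deliberately: the
ensemble is dilute and interaction-free, so the inter-particle structure
factor is flat.  The default evaluation path histograms the pair distances
(bin width 0.02 nm) and transforms the histogram; the direct $O(m^2)$
double sum is retained as the exact reference and the two agree to within
0.2% at the default bin width.

The $m$-point representation has a sampling floor: the expected discrete
intensity is $P(Q) + (1-P(Q))/m$, which matters only where $P(Q) \lesssim
1/m$.  The floor is shared by both reference ensembles entering the
mixture fit, so it cancels there, but for validation against the
closed-form orientation-averaged cylinder form factor the package offers
`self_term = FALSE`, which normalizes the $i \neq j$ sum by $m(m-1)$ — an
unbiased estimator of the continuum curve.  With $10^5$ independent
single-cylinder clouds of 100 points and 0.002 nm bins, the estimate
matches the quadrature form factor within 1% everywhere below
$Q = 3\ \mathrm{nm}^{-1}$, including the deep form-factor minimum.

### Analysis transforms

* **Guinier fit** (`guinier_rg()`): weighted linear fit of $\ln I$ vs
  $Q^2$ with automatic window selection — candidate windows are scanned,
  those with $Q_{max} R_g$ beyond 1.3 (the globular convention,
  configurable) or a positive slope are discarded, and the longest
  admissible window with acceptable quality wins.  A runs-test statistic
  on the residual signs is reported to expose curvature hiding in a
  formally acceptable window.
* **Pair-distance distribution** (`pofr()`): regularized indirect Fourier
  transform on $[0, D_{max}]$ with fixed zero endpoints and a
  second-difference smoothness penalty.  The weight is chosen as the
  largest value whose misfit stays within 10% of the best attainable
  misfit — an L-curve-style consistency heuristic that degrades gracefully
  from noiseless to noisy data.  Negativity of $p(r)$ is not hard-forbidden
  (spurious small negative lobes indicate over-aggressive $D_{max}$ or
  noise).  The real-space radius of gyration is
  $R_g^2 = \int r^2 p\,dr / (2\int p\,dr)$; on synthetic monomer profiles
  the reciprocal- and real-space estimates agree within the few-percent
  band expected of monodisperse data.
* **Kratky transform** (`kratky()`): $Q^2 I(Q)/I(0)$, with $I(0)$ taken
  from the Guinier fit.  `kratky_features()` counts structural features
  (maxima plus shoulders, the latter detected as positive local minima of
  the log-$Q$ derivative followed by a substantial recovery): one for a
  compact globular ensemble, two for an unstacked two-domain dimer.

## Fitting experimental profiles

**Stacked fraction.**  A measured dimer profile is modelled as
$I(Q) = A\,(p_{st} I_0(Q) + (1-p_{st}) I_\infty(Q)) + bckg$, where $I_0$
and $I_\infty$ are the simulated fully stacked and stacking-free reference
intensities.  `fit_pst()` reparametrizes to $a_0 = A p_{st}$,
$a_1 = A(1-p_{st})$ and solves a weighted linear least-squares problem with
non-negativity enforced by an exact active-set step, so
$p_{st} = a_0/(a_0+a_1)$ lies in $[0,1]$ by construction; boundary
solutions are flagged rather than hidden.  Simulated curves are
interpolated onto the experimental grid with shape-preserving monotone
splines and never smoothed — precision is bought with more configurations,
not filtering, to avoid biasing $\chi^2$.

**Inter-unit distance.**  The ratio of the free-dimer intensity to a
ligand-bound intensity cancels the (assumed common) form factor and leaves
the two-unit structure-factor ratio
$$ R(Q) = k\,\frac{1 + \mathrm{sinc}(Q R_{cm,T})}{1 +
   \mathrm{sinc}(Q R_{cm,T+L})}, $$
with the effective center-of-mass distances as parameters.
`fit_ratio()` fits all ratio datasets simultaneously with a shared
$R_{cm,T}$ by multi-start Levenberg–Marquardt.  The scale $k$ is fitted per
dataset by default (its volume-ratio interpretation is not imposed as a
constraint), with an option to share it; the distances carry a
configurable sanity ceiling of $2H + 2R_{HC}$.  Ratio points whose
propagated relative error exceeds 50% are truncated.  Across synthetic
ensembles of increasing stacked fraction, the fitted distance decreases
monotonically — the compaction linkage the model is built to quantify.

**Geometry search.**  `grid_search_geometry()` scans $R_{HC}$ over
1.18–1.26 nm in 0.01 nm steps; for each radius it examines heights in
0.06 nm increments centered on the constant-$R_g$ value
$H(R_{HC}) = \sqrt{12(R_{g,ref}^2 - R_{HC}^2/2)}$, runs both reference
ensembles, and ranks candidates by the reduced $\chi^2$ of the mixture
fit.

## CD melting analysis

A melting experiment yields an ellipticity matrix $D$ (wavelengths
$\times$ temperatures, typically 220–330 nm and 24–100 °C in 2 °C steps).
`svd_decompose()` factorizes $D = USV^T$ with a deterministic sign
convention.  A component is **significant** when its relative variance
$S_j^2/\sum S^2$ exceeds a floor (default 0.1%, configurable — the
criterion in the melting-SVD literature leaves the exact floor open) *and*
the lag-1 autocorrelations of both its basis spectrum and its amplitude
profile exceed 0.8; smooth signal vectors score near 1, noise near 0.
Counting stops at the first failure, so the result is the number of
leading signal components.

The significant amplitude vectors (weighted by their singular values) are
fitted globally by a sequential three-state unfolding model,
$F \rightleftharpoons I \rightleftharpoons U$, with van't Hoff equilibrium
constants $K_i(T) = \exp[-\Delta H_i/R\,(1/T - 1/T_{m,i})]$ (kelvin
internally, Celsius reported).  The per-component linear amplitudes are
profiled out at every step (variable projection), leaving four shared
thermodynamic parameters; $T_{m,2}$ is parametrized as $T_{m,1} + \Delta T$
with $\Delta T \ge 0$ so the transitions are ordered by construction, and a
grid of multi-starts guards against local minima.  A four-state variant is
deliberately *not* provided: the three-state model is the package's single
comparison framework across samples.  Because experiments quote one
melting temperature per sample, the **headline $T_m$** is defined as the
temperature where the folded fraction crosses one half.  Each dataset is
fitted independently; coupling related samples in one likelihood is left
to the user.

Spectral dissimilarity between two CD spectra on a common wavelength grid
is the root of the summed squared pointwise differences (`rsq()`, in
mdeg) — a metric (the suite property-tests symmetry and the triangle
inequality), used to rank how strongly a ligand remodels the G4 topology.

## The synthetic-data generators

The generators stand in for the experimental measurements and define the
conditions under which every recovery test runs.

* `gen_saxs()` runs the two reference ensembles, mixes them at a known
  $p_{st}$, and applies Gaussian noise with relative standard deviation
  $\alpha + \beta/\sqrt{I(Q)/I(0)}$ ($\alpha = \beta = 0.005$): about 1% at
  low $Q$, growing where the signal fades, the error structure typical of
  synchrotron bioSAXS on the measured 0.044–5.21 nm$^{-1}$ range.
* `gen_ratio()` evaluates the closed-form ratio model at known distances
  (defaults 3.59 and 3.18 nm, the scale of free and strongly compacted
  telomeric dimers) with 1% relative noise.
* `gen_cd_melt()` builds $D = B\,F(T)$ + noise from Gaussian-band basis
  spectra and three-state fractions.  The folded basis mimics a hybrid G4
  (maximum at 290 nm, shoulder at 270 nm, minimum at 240 nm), the
  intermediate a parallel-like species (maximum near 265 nm), and the
  unfolded state a weak residual spectrum — strong enough that all three
  species are resolvable, which is the generator's purpose.  Default
  thermodynamics ($\Delta H_1 = 200$ kJ/mol, $T_{m,1} = 62.5$ °C,
  $\Delta H_2 = 250$ kJ/mol, $T_{m,2} = 70$ °C) place the headline $T_m$
  near 62 °C, typical of free telomeric G4s in potassium buffer.  Noise is
  0.15 mdeg.

Every generator returns a machine-readable truth record, and recovery
tests read the truth only through it.  What the generators do *not*
emulate: instrument smearing and beam geometry, aggregation artifacts,
inter-particle interference, concentration-series effects, or sloping CD
baselines.  Passing recovery tests therefore demonstrates correctness of
the inference machinery under the stated noise model, not robustness to
every experimental pathology.

## Problem sizes and numerical defaults

Simulation defaults are a desk-scale profile: 300 dimers, 400
thermalization sweeps, 10 snapshots 20 sweeps apart, 50 points per
cylinder in the generators.  The experimental-scale profile of the
workflow this package systematizes (3000 dimers, $\ge 5\times10^5$ MC
steps, 50 snapshots, 100 points per cylinder) is available via
`experimental_scale = TRUE` in `gen_saxs()` or explicit configuration.  The
validation studies in the test suite and acceptance script choose sizes so
that each statistical comparison has several standard errors of headroom:
e.g. $4\times10^5$–$8\times10^5$ proposals for the geometric oracle, 60
snapshots of 400 dimers for the $T^* = \infty$ comparison (the stacking
probability being $\sim 6\times10^{-4}$, smaller runs would be
shot-noise-dominated), and $10^5$ hundred-point clouds for the form-factor
cross-check.

Other numerical choices: GJK separation tolerance $10^{-10}$ nm;
pair-histogram bins 0.02 nm for analysis (0.002 nm for form-factor
validation); Guinier $Q R_g$ ceiling 1.3; IFT grid of 101 $r$-points and a
25-point logarithmic regularization scan; ratio and three-state fits use
8–9 multi-starts with box bounds, and report covariance-based
uncertainties scaled by the reduced $\chi^2$.

## Known limitations

The hard-cylinder model deliberately ignores G4 fine structure: topology
changes (hybrid/antiparallel/parallel), ligand binding modes, and the
hydration shell are invisible to it, which is precisely why the high-$Q$
region of real data is reproduced only approximately.  The two-state
intensity decomposition assumes the stacked and unstacked sub-ensembles of
a ligand-bound sample are those of the reference simulations.  The ratio
model assumes a common form factor between free and bound dimers and a
single effective inter-unit distance.  The CD analysis assumes
temperature-independent basis spectra and unimolecular sequential
transitions — bimolecular or kinetically limited melts violate it.  None
of these assumptions are checked by the package; they are the model.
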