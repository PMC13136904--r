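# g4dimer

Coarse-grained simulation and SAXS/CD analysis of telomeric G-quadruplex
dimers.

## The problem

Long telomeric overhangs fold into tandem G-quadruplex (G4) units that can
stack at their interface, and G4-binding ligands shift the
stacked/unstacked equilibrium — a compaction that small-angle X-ray
scattering (SAXS) sees directly, and whose thermodynamic side circular
dichroism (CD) melting experiments report.  Turning those measurements into
numbers (a stacked fraction, an inter-unit distance, melting temperatures)
requires an ensemble model and a fitting pipeline.  `g4dimer` provides
both, for structural biophysicists working on G4 multimers or on ligand
design against them.

## The model

Each G4 unit is a hard cylinder (radius `R_HC = 1.26` nm, height
`H = 2.64` nm by default).  A dimer is two cylinders joined by an infinite
square well of width `2*R0` (`R0 = 0.53` nm) between rim-mounted linker
patches — the TTA linker — plus a finite square well of width `2*R1`
(`R1 = 0.265` nm) and depth `u0` between the facing base centers — the
stacking interaction.  The dimensionless temperature `T* = kB*T/u0`
controls stacking: `T* = 0` gives fully stacked dimers, `T* = Inf` removes
the bias.  Canonical Metropolis Monte Carlo over independent dimers yields
ensembles; Debye sums over point-decorated cylinders yield model
intensities; and a measured profile is decomposed as

    I(Q) = A * ( p_st * I_0(Q) + (1 - p_st) * I_inf(Q) ) + bckg

to estimate the stacked fraction `p_st`.  Dimer compaction is quantified
independently through the intensity ratio of free to ligand-bound dimers,

    R(Q) = k * (1 + sinc(Q * R_cm_T)) / (1 + sinc(Q * R_cm_T+L)),

whose fit returns the effective distances `R_cm` between the centers of
mass of the two units.  Standard SAXS transforms (automatic Guinier fits,
regularized p(r) inversion, dimensionless Kratky plots) and a CD melting
suite (SVD with autocorrelation-based component counting, a global
three-state van't Hoff fit, the RSQ spectral dissimilarity) complete the
pipeline.  Synthetic-data generators emulate both experiment classes at
known ground truth.

## Worked example

```r
library(g4dimer)

# a synthetic dimer SAXS measurement at known stacked fraction 0.5
synth <- gen_saxs(p_st_true = 0.5, seed = 1)

fit_pst(synth$i_exp, synth$i0, synth$i_inf)
#> p_st = 0.513 +/- 0.014 (A = 0.998, bckg = 8.04e-05, chi2_red = 0.919)

guinier_rg(synth$i_exp)        # mixed ensemble
#> Guinier fit: Rg = 1.995 +/- 0.009 nm, I(0) = 0.9979 (108 pts, q*Rg <= 1.14)
guinier_rg(synth$i_inf)        # stacking-free ensemble is less compact
#> Guinier fit: Rg = 2.108 +/- 0.001 nm, I(0) = 0.9989 (108 pts, q*Rg <= 1.21)

# inter-unit distance from a synthetic free/bound intensity ratio
fit_ratio(gen_ratio(r_cm_t = 3.59, r_cm_tl = 3.18, k = 1, noise = 0.01, seed = 1))
#> Ratio fit: shared R_cm_T = 3.568 +/- 0.010 nm, chi2_red = 0.835
#>    r_cm_tl  r_cm_tl_se        k         k_se
#> 1 3.161416 0.009137698 1.000003 0.0007436222

# CD melting: count species, fit the unfolding thermodynamics
cd <- gen_cd_melt(seed = 1)
sv <- svd_decompose(cd$matrix)
significant_components(sv)
#> [1] 3
fit_three_state(sv)
#> Three-state fit (3 components): dH1 = 200 kJ/mol, Tm1 = 62.5 C;
#> dH2 = 246 kJ/mol, Tm2 = 69.9 C; headline Tm = 62.0 C
```

The mixture fit recovers the generating stacked fraction within its
uncertainty; the Guinier radii show the stacked/unstacked compactness
ordering; the ratio fit returns the free and compacted inter-unit
distances it was generated from; and the CD analysis finds three
spectroscopic species and the generator's transition midpoints.

Experimental three-column `.dat` profiles (e.g. from the small-angle
scattering databank) are read with `read_saxs_dat()`, CD melting matrices
with `read_cd_matrix()`, and the same fitting functions apply; simulated
reference intensities for `fit_pst()` come from `run_mc()` +
`simulate_intensity()` at `tstar = 0` and `tstar = Inf`.

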