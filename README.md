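# fibrilscatter

Inference of cellulose microfibril structure from one-dimensional
fibre-diffraction profiles: wide-angle X-ray (WAXS), wide-angle neutron
(WANS) and small-angle neutron (SANS) scattering. The package is aimed at
plant cell-wall and biomass researchers who have azimuthally integrated
radial profiles (q in nm⁻¹ vs intensity) from well-oriented fibre samples
and want microfibril dimensions, lattice geometry and packing numbers out
of them — together with a seeded synthetic-pattern generator so every
analysis stage can be validated by parameter recovery on data with known
ground truth.

## The models at the core

**Equatorial WAXS.** The equatorial profile is decomposed into the 1-10 and
110 reflections (Gaussians, strongly overlapped at small monoclinic
angles), the 200 reflection with the asymmetric shape

    F(q) = F0(q)                           for q ≥ q0
    F(q) = F0(q) · (1 + 0.1 (q − q0)²)     for q < q0,

where F0 is a Gaussian and the constant 0.1 nm² is fixed, plus a Gaussian
400 and an optional weak 100 shoulder near q = 8 nm⁻¹, over a
power-law-plus-constant diffuse background fitted jointly. Crystallite size
and paracrystalline disorder are separated through the integral widths
δq = area/height of the symmetric parts:

    δq = δq₀ + (π/2) g² q₀² d,    L = 2π/δq₀,

a straight line in q₀²d whose intercept gives the Scherrer column length L
perpendicular to the [200] plane and whose slope gives the disorder
parameter g.

**Lattice geometry.** Equatorial spacings follow the oblique hk0 cell
(1/d² = [h²/a² + k²/b² − 2hk·cosγ/(ab)]/sin²γ); the fitted (d₁₋₁₀, d₁₁₀,
d₂₀₀) triple is inverted in closed form to (a, b, γ) with the reporting
convention γ ≥ 90°. Per-chain cross-section a·b·sinγ/2 (two chains per
cell) and floor(envelope area / chain area) give microfibril chain counts.

**SANS.** The interfibril Bragg peak is fitted as a Gaussian over a
power-law background; the centre gives the centre-to-centre spacing
d = 2π/q_peak across a D₂O hydration series. Scattering-length densities
from coherent b values give the D₂O:H₂O contrast-match fraction
f = (ρ_cell − ρ_H₂O)/(ρ_D₂O − ρ_H₂O).

**WANS.** Cuboid-sample absorption correction by path-length quadrature,
D−H difference profiles (deuteration of accessible hydroxyls suppresses
the 1-10 and boosts the 200), a joint H/D fit under the shared-lattice
hypothesis, and detection of meridional 00l reflections that appear only
after deuteration.

## Worked example

Run the full synthetic study — generate WAXS/SANS/WANS data from the
default bamboo-like ground truth, analyse every arm, and derive the
geometry:

```r
library(fibrilscatter)
report <- run_study(study_config(seed = 42))
report
#> <study_report>
#>   WAXS: d200 = 0.4030 nm, gamma = 92.4 deg, L = 3.83 nm, g = 0.0354
#>   SANS: spacing 2.96/3.05/3.19 nm at fractions 0/0.1/0.25; match at 35% D2O
#>   WANS: lattice consistency pass; 00l detected: 1, 2
#>   Geometry: 0.330 nm^2 per chain; 34 chains (rectangle), 26 (ellipse)
```

Reading the numbers: the intersheet spacing d₂₀₀ = 0.403 nm and monoclinic
angle ≈ 92° recover the generating lattice; the disorder-corrected column
length L ≈ 3.8 nm is the mean microfibril dimension perpendicular to the
sheets of chains; the SANS peak moves from 2.96 nm (dry) to 3.19 nm (25%
D₂O), the centre-to-centre distance across the sheets; the 35% D₂O match
point confirms the scatterer has the scattering-length density of
cellulose; the deuterated-only 001/002 meridional detections indicate
stagger disorder of surface chains; and a 3.8 × 3.0 nm cross-section at
0.33 nm² per chain holds 34 chains (26 for an elliptical envelope).

Individual stages compose with pipes and have `tidy()`/`glance()`/
`autoplot()` methods:

```r
profile <- generate_equatorial_waxs(ground_truth(seed = 1))
fit <- analyze_equatorial_waxs(profile)
glance(fit$broadening)
#> # A tibble: 1 × 5
#>       L      g delta_q0   slope n_points
#>   <dbl>  <dbl>    <dbl>   <dbl>    <int>
#> 1  3.82 0.0356     1.64 0.00199        2
autoplot(fit$equatorial)
```

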