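---
title: "Models and numerical methods in sedstoich"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and numerical methods in sedstoich}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sedstoich)
```

`sedstoich` implements the quantitative chain used to characterize
protein–ssDNA complexes by analytical ultracentrifugation (AUC) and
static light scattering: forward simulation of sedimentation-velocity
(SV) scans, inversion into c(s) sedimentation-coefficient
distributions, global sedimentation-equilibrium (SE) fitting with
mass-conservation constraints, buoyancy bookkeeping, stoichiometry
enumeration, and titration normalization with aggregation-onset
detection. This vignette explains the models, the tunable parameters,
and the numerical choices, so that results can be interpreted and the
package extended with confidence.

## Units

All arithmetic is CGS: radii in cm, time in s, energies in erg, with
the gas constant $R = 8.31446\times 10^{7}$ erg mol$^{-1}$K$^{-1}$.
Sedimentation coefficients are handled in Svedberg
($1\,\mathrm{S} = 10^{-13}$ s) at the user interface and converted to
seconds internally. Angular velocity is $\omega = 2\pi\,\mathrm{rpm}/60$.
Concentrations of oligonucleotides are molar in *molecules*, never in
nucleotides; nucleotide-unit inputs must be converted at the registry
boundary with an explicit length, which avoids silent 15–140-fold
errors when mixing conventions.

## Buoyancy bookkeeping

A complex of $n_i$ copies of components with molar masses $M_i$ and
partial specific volumes $\bar v_i$ has the additive partial specific
volume

$$\bar v = \frac{\sum_i n_i M_i \bar v_i}{\sum_i n_i M_i},$$

implemented in `composite_vbar()`. The buoyant molar mass is
$M(1-\bar v \rho)$ with $\rho$ the solvent density. Component masses
can be entered directly or derived from residue sequences
(`molar_mass_from_sequence()`): average residue masses with one
terminal water for peptides, and 5'-OH/3'-OH oligonucleotides built
from nucleoside masses plus one phosphodiester linkage mass
(61.96 g/mol) per internal bond. The Cy3 label is a documented adduct
constant (507.3 g/mol, the phosphoramidite-coupled dye including its
phosphate linker); the underlying study does not state the oligo end
chemistry, so these conventions are package definitions, asserted
exactly by the concatenation-additivity test.

Masses that are only printed as complex totals are recovered with
`derive_component_masses_from_complexes()`, a least-squares solve of
the linear system formed by composition patterns and total masses.
The shipped `example_registry()` does exactly this: the single-protein
complex total fixes the protein + peptide + labelled-DNA group, and
the difference between the large-complex and small-complex totals
fixes four copies of the second protein.

## The Lamm equation solver

SV scans are modelled by the Lamm equation in a sector-shaped cell,

$$\frac{\partial c}{\partial t} = \frac{1}{r}\frac{\partial}{\partial r}
  \left[ r D \frac{\partial c}{\partial r} - s\omega^2 r^2 c \right],$$

with zero-flux walls at the meniscus and the cell bottom and a uniform
initial loading. The discretization is a conservative finite-volume
scheme on a uniform radial grid (default 400 cells over a 6.0–7.2 cm
column, matching the 0.003 cm scan interval of absorbance optics),
with Scharfetter–Gummel exponential-fitted face fluxes and implicit
(backward Euler) time stepping, default maximum step 20 s. This
combination was chosen for three properties that the tests assert
directly:

* **exact mass conservation** — fluxes telescope, so the sector
  integral $\sum_j c_j r_j \Delta r$ is conserved to rounding error;
* **unconditional positivity** — the step matrix is an M-matrix, so
  noiseless solutions can never go negative, also for stiff
  high-$s$ species;
* **unconditional stability** — no CFL restriction, so one default
  step size serves the whole 0.2–12 S kernel range.

The price is first-order accuracy in time; the default step is small
enough that halving both the grid spacing and the step changes scans
by well under 0.2% RMS of the loading signal over the analysis region.
The thin back-diffusion layer at the cell bottom (a few times
$D/(s\omega^2 r)$ wide, often under 100 µm) holds a near-singular
equilibrium gradient; like all scan analyses we regard the last
fraction of a millimetre as outside the analysis region, and the
self-convergence test excludes it.

Diffusion coefficients come from the standard c(s) parameterization:
one frictional ratio $f/f_0$ (default 1.2) shared by all species, with
$M(s)$ from the Svedberg relation and a Stokes sphere of the anhydrous
radius, so $D = k_B T / (6\pi\eta (f/f_0) R_0)$ (`species_from_s()`).
The study prints no $D$ values, so this mapping is the only source of
diffusion in the synthetic data.

## c(s) inversion

`fit_cs()` models the scan set as a non-negative superposition of
single-species Lamm solutions on a fixed $s$ grid (default 100
log-spaced points over 0.2–12 S, covering all values reported for
this system, 0.5–6.3 S), plus two systematic baselines: a
time-invariant radial baseline and a per-scan radially invariant
offset, the standard TI/RI decomposition for absorbance optics drift.
Because the scan grid is balanced (every scan shares the radius grid),
the baseline subspace is projected out exactly by double centering,
after which the amplitudes solve a non-negative least-squares problem
(Lawson–Hanson, via `pracma::lsqnonneg`) with a second-difference
smoothness penalty.

The regularization strength follows the usual c(s) criterion: the
largest $\alpha$ whose $\chi^2$ stays within an F-ratio envelope of
the unregularized $\chi^2$ at confidence 0.68 (configurable). The
search is a deterministic sweep over log-spaced candidates scaled to
the kernel norm. Increasing $\alpha$ can only increase the fit RMSD;
the property suite asserts this monotonicity together with amplitude
non-negativity.

`weight_average_s()` integrates $\int s\,c(s)\,ds / \int c(s)\,ds$ by
the trapezoidal rule over the full grid unless a range is given (the
averaging window used in the study is not defined, so the full grid is
the default). `peak_fraction()` splits the integrated area at a
boundary with linear interpolation inside the straddling interval; the
two fractions sum to one exactly by construction.

## Global sedimentation-equilibrium fitting

At equilibrium an ideal species forms the exponential profile

$$A(r) = A_{r_0}\exp\!\left[ M (1-\bar v \rho)
  \frac{\omega^2}{2RT}\left(r^2 - r_0^2\right) \right] + b_r,$$

with $b_r$ one baseline offset per profile (the conventional reading
of a radially dependent offset; a linear-in-$r$ option is a possible
extension but is not needed for short columns). `fit_one_species_global()`
fits one shared $M$ across all rotor speeds. With mass conservation
(the default) the per-speed amplitudes are reparameterized by a single
loading parameter $W$ — the sector-integrated, baseline-subtracted
signal — so the fitted loading is speed-invariant *by construction*,
which the tests assert to $10^{-6}$ relative.

The optimization exploits the model structure: for fixed $M$ every
remaining parameter (loading or amplitudes, baselines) is linear, so
the problem reduces to one dimension by variable projection. A coarse
deterministic grid on $\log M$ over $10^3$–$10^7$ g/mol followed by
local refinement replaces the usual multi-start trust-region schedule
and cannot be trapped by a poor single start. Design columns are kept
on a bounded scale (each exponential is normalized by its sector
integral, or its maximum, with the log shift stored), so trial masses
far from the optimum cannot overflow. Standard errors are 1 SE from
the Jacobian-based covariance scaled by the reduced $\chi^2$, computed
through $\log M$ and transported by the delta method; the report
labels them as 1 SE. Fitted $M$ is invariant to the choice of
reference radius $r_0$ (asserted to $10^{-6}$ relative), since the
amplitude reparameterizes.

`fit_two_species_global()` adds a second species (typically unbound
DNA with fixed, known mass) with non-negative amplitudes; an amplitude
driven to zero is a boundary solution, not a failure. On short
equilibrium columns the free-DNA exponential is shallow and therefore
nearly collinear with the per-speed baselines, which makes the
unconstrained minor-species fraction a heavy-tailed statistic: pure
noise can masquerade as a few percent of "DNA". The fitter therefore
applies a parsimony rule by default: the minor species is retained
only when removing it worsens the fit by more than an F-test at 0.95
confidence; otherwise the boundary solution is reported. A genuine
mixture passes this test by orders of magnitude (the 50:50 recovery
test), while noise-only contributions are pinned to zero. The rule can
be disabled (`parsimony = FALSE`) to inspect the raw estimate.

## Stoichiometry enumeration

`enumerate_matches()` walks the bounded integer lattice of copy
numbers, applies declarative constraints (allowed copy sets such as a
tetramer-only rule, and inequalities such as "at most one peptide per
protein"), and ranks candidates by $|{\sum_i n_i M_i - M_{fit}}|$ with
deterministic lexicographic tie-breaking. A candidate is *within
window* when its deviation is at most `window_k` standard errors;
the default `window_k = 2` is deliberate: assignments of this kind are
routinely quoted "within error" at two standard errors, and a 1-SE
window would reject assignments that the field accepts (the motivating
case sits between 1 and 2 SE of its fitted mass). The enumeration is
pure mass bookkeeping; no thermodynamic preference between candidate
compositions is modelled.

## Titration normalization and onset detection

Light-scattering titrations are normalized as
$I_{i,\mathrm{norm}} = (I_i - I_0)/I_0$ with optional buffer-reference
subtraction (reference increments interpolated onto the sample ratio
grid) and optional $V_i/V_0$ dilution correction, which is off by
default since injection volumes are usually folded into the reported
concentrations. The aggregation onset is an empirical changepoint, not
a kinetic model: a continuous two-segment hinge fitted by exhaustive
breakpoint search over the observed molar-ratio grid, refined
parabolically between the best three grid SSE values. Detection
requires the hinge to beat a single straight line by an F-ratio
(default 4.0 with at least 4 points per segment) *and* a post-onset
slope exceeding the pre-onset slope; the threshold is conservative
against noise-only false positives, which a seeded property test
verifies. Whether published onset ratios were read from normalized or
raw curves is ambiguous; the detector runs on the normalized scale by
default and works identically on raw intensities.

The 1:1 binding saturation uses the exact quadratic: the complex
concentration is the smaller root of
$C^2 - (R_t + L_t + 1/K)C + R_t L_t = 0$, evaluated in the
subtraction-free form $C = 2R_tL_t/(b + \sqrt{b^2 - 4R_tL_t})$.

## The synthetic-data generator

No raw scans are publicly deposited for this system, so the generator
is a first-class module that emulates the study conditions:

* **SE datasets** — closed-form exponential profiles at 18 000/23 000/
  28 000 rpm on a short (6.9–7.2 cm) column scanned at 0.003 cm, with
  per-speed baselines drawn uniformly from ±0.01 AU and i.i.d.
  Gaussian noise, default $\sigma = 0.005$ AU (typical absorbance
  noise; swept 0.002–0.01 by a property test). Amplitudes derive from
  one shared loading, so mass conservation is exact in the noiseless
  limit. The closed form is used deliberately — never the Lamm
  solver — so SE round trips are independent of PDE discretization
  error.
* **SV datasets** — Lamm-solver scans at 42 000 rpm with a schedule
  spread until the non-diffusing boundary of the principal species
  would cover 90% of the column.
* **Titrations** — flat-then-rising hinges on the normalized scale
  (zero mean below the onset, default slope 0.8 above, noise 0.02),
  reconstructed into raw intensities so they round-trip through the
  normalizer.

`paper_scenarios()` names the study conditions: SE scenarios at the
expected complex masses 33.8, 69.5 and 121.5 kDa with composite vbars
from the printed component values (0.734, 0.711, 0.704, 0.56 ml/g),
SV scenarios at each reported weight-average coefficient, and
titration hinges at onset ratios 5.2, 6 and 7.1. Where the source
reports both 121.2 and 121.5 kDa for the same complex, the scenario
generates at the figure-legend value (121.5); the stoichiometry tests
tolerate the 0.3 kDa discrepancy explicitly. The solvent is described
by a density of 1.05 g/ml and viscosity of 0.020 poise at 298.15 K —
realistic for a 25% (v/v) glycerol buffer at 25 °C, neither value
being printed; mass recovery is invariant to this shared choice, which
a test asserts at 1.02 and 1.08 g/ml.

Every generator is seeded and bit-reproducible, and every synthetic
manifest records its seed. What passing round-trip tests show is that
the *analysis chain is self-consistent under the stated noise model*;
they cannot show robustness to features real data have and the
generator does not emulate: optical convolution, rotor acceleration
and wobble, approach-to-equilibrium transients, concentration-dependent
non-ideality, or reaction boundaries of interacting systems — all
deliberately out of scope.

## Problem sizes

The test suite and the acceptance script run the chain at sizes chosen
for tight feedback while leaving every assertion meaningful: SE fits
use the full 0.003 cm grid (101 points × 3 speeds); c(s) round trips
use 40–60 point s grids with 240–300 finite-volume cells and 8 scans;
the full default resolution (100 s points, 400 cells) behaves
identically and is exercised by the boundary-velocity and convergence
tests. Recovery assertions are statistical (2 fitted SE) under fixed
seeds.

## Known limitations

* Ideal, non-interacting species only; no association models, no
  floating $\bar v$, no meniscus refinement.
* The bottom boundary layer in SV scans is resolution-limited; scans
  within ~0.05 cm of the bottom should not be interpreted.
* The parsimony F-test assumes i.i.d. Gaussian residuals; strongly
  correlated optical noise would change its calibration.
* Buffer density/viscosity and component vbars are inputs; the package
  does not estimate them from composition.
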