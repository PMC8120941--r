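---
title: "Porosity and pore-shape analysis with the anisotropic Bruggeman model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Porosity and pore-shape analysis with the anisotropic Bruggeman model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(porethz)
```

## The model

Terahertz time-domain spectroscopy measures the effective refractive
index $n_\mathrm{eff}$ of a tablet in transmission. For a two-phase
compact of air pores in a solid matrix, the anisotropic Bruggeman
effective medium approximation (AB-EMA) ties $n_\mathrm{eff}$ to the
porosity $f$, the intrinsic refractive index of the fully dense solid
$n_s$, and a depolarisation factor $L$ describing the pore shape:

$$
f\,\frac{1 - n_\mathrm{eff}^2}{n_\mathrm{eff}^2 + L\,(1 - n_\mathrm{eff}^2)}
+ (1 - f)\,\frac{n_s^2 - n_\mathrm{eff}^2}
                {n_\mathrm{eff}^2 + L\,(n_s^2 - n_\mathrm{eff}^2)} = 0 .
$$

The pores are spheroids with their polar axis along the wavevector;
$L = 1/(1 + 1.6\,x + 0.4\,x^2)$ maps the polar-to-equatorial aspect
ratio $x$ to $L$: $1/3$ for spheres, $\to 0$ for needle-like prolates,
$\to 1$ for flat oblates. The equation is quadratic in
$n_\mathrm{eff}^2$ and *linear* in each of $f$, $n_s^2$ and $L$, so all
single-unknown inversions used in this package are closed forms
(`neff_forward()`, `porosity_from_neff()`, `ns_from_neff()`,
`depolarisation_from_sample()`); nothing is fitted iteratively at the
level of a single sample. The complex variant replaces the squared
indices by complex permittivities $\tilde\varepsilon = (n - i\kappa)^2$
and stays linear-fractional in the solid permittivity
(`eps_s_from_eps_eff()`), with $\kappa = c\,\alpha/(4\pi\nu)$ converting
an absorption coefficient (cm$^{-1}$) at frequency $\nu$ (THz) into an
extinction coefficient.

The Wiener bounds - the serial and parallel capacitor extremes
$n_{\mathrm{eff},l}^2 = 1/(f + (1-f)/n_s^2)$ and
$n_{\mathrm{eff},u}^2 = f + (1-f)\,n_s^2$ - coincide with the AB-EMA at
$L = 1$ and $L = 0$. The forward solver exploits this: the physical
root of the quadratic is the one inside the Wiener bracket, and the
endpoints are evaluated through the Wiener closed forms directly so no
0/0 arises as $L \to 0$ or $1$.

## Fitting a tablet set

Given a set of $(f, n_\mathrm{eff})$ pairs, `fit_abema()` scans $L$
over a grid (default step 0.001), inverts the model per sample for the
implied $n_s$, and keeps the $L$ at which those per-sample values
scatter least (standard deviation); $n_{s,\mathrm{fit}}$ is their mean.
Ties go to the smallest $L$, making the output deterministic. Grid
values at which any sample implies $n_s^2 \le 1$ are excluded as
non-physical; a fit where the whole grid is excluded is reported as
failed rather than returning a nonsense optimum. On noiseless
model-consistent data whose $L$ lies on the grid the objective reaches
its floating-point floor (about $10^{-8}$, the cancellation limit of
the streaming variance) and the generating parameters are recovered
exactly:

```{r fit}
set <- gen_set(1.86, 0.5, seq(0.05, 0.5, by = 0.05))
fit_abema(set)
```

Two extensions cover common experimental situations:

* `fit_abema_shared()` fits several sets of the *same material* jointly,
  with one $L$ per set but a single shared $n_s$, minimising the pooled
  squared deviation of all per-sample $n_s$ values about the global
  mean. Pairs of sets are solved by exhaustive search over both grids;
  larger collections by coordinate descent, which on these smooth
  objectives converges in a handful of sweeps.
* `fit_mabema()` (modified AB-EMA) replaces the constant $L$ by
  $L(f) = a_1 f + a_2$, constrained to $[0, 1]$ at the sample
  porosities. A coarse grid (0.02 in $a_1$, 0.005 in $a_2$) seeds a
  Nelder-Mead refinement; the constant-L optimum is always included as
  a candidate, so the modified model never fits worse than the scalar
  model it nests.

Goodness of fit is reported two ways (`goodness()`): the adjusted
$R^2$ of measured vs fitted $n_\mathrm{eff}$, with $p = 2$ parameters
for the constant-L model and $p = 3$ for the modified model (the
standard $1 - (1 - R^2)(n-1)/(n-p-1)$ definition), and the RMSE of the
*porosity* in percentage points - the independent variable - because in
practice the calibration is used to predict porosity from a measured
index (`predict_porosity()`).

## Bounds for the depolarisation factor

$n_s$ is a material constant but rarely measurable directly, since a
zero-porosity compact is experimentally inaccessible. The
lowest-porosity sample, where the Wiener bounds are tightest, pins it
into margins (`ns_margins()`): the index the solid would need if that
sample's pores were extreme oblates ($L = 1$, giving $n_{s,u}$) or
extreme prolates ($L = 0$, giving $n_{s,l}$). Substituting each margin
into the single-sample inversion for $L$ yields, for every other
sample, an interval $[L_l, L_u]$ that the true depolarisation factor
must occupy (`l_bounds()`). The anchor sample itself carries no shape
information and yields $(0, 1)$ by construction. For model-consistent
data the intervals tighten monotonically with porosity and always
contain the truth; both properties are asserted in the test suite on
randomized sets.

```{r bounds}
b <- l_bounds(set)
b$table[c(1, 2, 10), c("f", "L_l", "L_u")]
```

The bounds double as a model-validity check (`validate_fit()`): a
fitted $L$ trajectory escaping $[L_l, L_u]$ at any sample is physically
impossible, and bounds that converge onto a steep gradient indicate a
pore shape changing with porosity, which the constant-L model cannot
represent. The steepness verdict uses the *mean* of the two bound
tangents taken over the two highest-porosity samples: before the bounds
have converged the individual tangents are steep even for constant-L
data over a narrow porosity range, while their mean already tracks the
common trend. The default threshold of 0.25 per unit porosity is a
package convention - the literature offers no numeric criterion - and is
configurable.

## The three error studies

`absorption_study()`, `poreshape_study()` and `density_study()`
quantify, on fully deterministic noiseless grids, the three error
sources that matter in practice. They involve no randomness, so their
reports are bit-reproducible and several are frozen into the test
suite.

**Absorption.** Ignoring the extinction coefficient biases the
extracted solid index. The study grids $\alpha_\mathrm{eff}$ from 0 to
50 cm$^{-1}$ (step 1), $n_\mathrm{eff}$ from 1 to 5 (step 0.1),
porosity 0.05-0.25 (step 0.05), frequencies 0.2 and 1 THz and three
pore shapes (aspects 5, 1, 1/5), solving the complex and the real model
in every cell and reporting $|n_{s,c} - n_s| / n_{s,c}$. The 0-50
cm$^{-1}$ range spans non-absorbing up to a worst case of roughly 1%
transmittance through a 1 mm compact. Typical errors are
$10^{-5}$-$10^{-3}$ - below the $10^{-4}$-$10^{-3}$ uncertainty of the
index extraction itself -, grow toward lower frequencies (since
$\kappa \propto 1/\nu$), and are smallest for spherical pores. Cells
where either inversion is non-physical (e.g. $n_\mathrm{eff} = 1$) are
flagged rather than dropped so the report stays rectangular.

**Pore-shape gradients.** 51 sets over porosities 0.05-0.5 (step 0.05)
with $n_s = 1.86$ (a standard value for microcrystalline cellulose) and
a linear $L(f)$: the endpoint $L$ values step in 0.02 from $(1, 0)$ to
$(0, 1)$, producing gradients $a_1$ from $-2.22$ to $+2.22$ in steps of
$0.04/0.45 = 0.0889$ with the porosity-averaged $L$ pinned at 0.5. Each
set is fitted with the constant-L model. The fitted $L$ escapes the
simulated $[L_{\min}, L_{\max}]$ range for most non-zero gradients,
$n_{s,\mathrm{fit}}$ is over-/underestimated for positive/negative
gradients, its relative error passes 2.5% near $|a_1| \approx 0.6$-$0.7$,
and the porosity RMSE peaks around 4% at the extreme gradients.

One published observation this package does *not* reproduce: the claim
that the constant-L fit retains an adjusted $R^2$ above 0.99 at every
gradient. A global scan over *all* $(L, n_s)$ pairs - not just the
std-of-$n_s$ optimum - shows that no constant-L curve can exceed
$\approx 0.95$ ($+$ side) or $\approx 0.91$ ($-$ side) adjusted $R^2$
against the $|a_1| = 2.04$ sets under the residual-based definition
(nor under a correlation-based one), so the claim is unattainable under
the stated simulation design. The study reports the honestly computed
values; above $|a_1| \approx 1.5$ they fall below 0.99. Relatedly, the
reported fit *failures* at gradients above 2.04 have no stated
criterion; here a fit fails only when every grid $L$ is excluded as
non-physical, which none of the 51 sets triggers - the per-set
`n_grid_excluded` and `failed` columns record what actually happens.

**Density distribution.** Biconvex tablets compact less at the centre,
and the beam probes exactly that centre column, while the nominal
porosity comes from whole-tablet mass and geometry. The study computes
$n_\mathrm{eff}$ at a centre porosity a relative 10% above/below
nominal (spherical pores, $L = 1/3$, $n_s = 1.86$) and fits against the
nominal porosity. The deviation is multiplicative - an additive reading
would push high-porosity samples past physical porosity - and 10% is a
realistic magnitude given finite-element studies reporting
centre-to-nominal differences up to 30%. The goodness of fit barely
moves (adjusted $R^2$ 0.9993/0.9997) but the fitted pore shape is badly
biased:

```{r density}
density_study(deviation = 0.10)
```

That is the practical warning of these studies: a high $R^2$ does not
certify the extracted $n_s$ and $L$. Calibrations should use flat-faced
tablets, and the bounds of the previous section should be consulted
before interpreting a fitted $L$ as a pore shape.

## Geometry, spectra and units

`porosity_flat()` and `porosity_biconvex()` derive the nominal porosity
from mass, tooling geometry and true density;
the biconvex volume is a cylinder of height $H - 2h$ plus two spherical
caps $\pi h^2 (3C - h)/3$, reducing continuously to the flat case at
$h = 0$. Inputs are unit-agnostic as long as they are consistent: grams
with centimetres, or milligrams with millimetres, both against g
cm$^{-3}$ (the conversion factors cancel, which the tests assert).
True densities are g cm$^{-3}$ throughout, e.g. 1.527 for
microcrystalline cellulose blends. `average_neff_band()` averages a
measured index spectrum over a closed band, by default 0.4-0.8 THz, the
conventional window where excipients absorb weakly.

## Numerical conventions and limitations

* Closed-form identities are asserted at $10^{-10}$ absolute on
  unit-scale quantities; the forward/inverse pair round-trips to that
  tolerance over randomized valid inputs, and the closed-form $L$ is
  checked against a $10^{-5}$-step brute-force residual scan.
* The quadratic in $n_\mathrm{eff}^2$ is solved with the
  sign-stabilised formula (the leading coefficient vanishes as
  $L \to 1$, and the linear coefficient can be exactly zero, e.g. at
  $f = 0.5$, $L = 0.5$).
* The complex square root uses the branch with positive real part,
  matching the $n - i\kappa$, $\kappa \ge 0$ convention.
* Generated sets are noiseless: passing parameter-recovery tests shows
  the estimators are exact on model-consistent data, not that they are
  robust to measurement noise; no noise model or uncertainty
  quantification (bootstrap intervals on $L_\mathrm{fit}$) is provided.
* Frequency-dependent dispersion and multicomponent mixtures beyond
  folding all solids into one $n_s$ are out of scope; the
  multicomponent Wiener bounds are provided for completeness but are
  deliberately not used inside the bounds-for-L machinery, which is a
  two-phase construction.
* Problem sizes: every analysis here runs in seconds on one CPU - the
  heaviest objects are the 62,730-cell absorption grid and 51 fits of a
  1001-point L-grid over 10 samples.
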