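---
title: "Modelling sunlit-shaded light dynamics in 3-D canopies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling sunlit-shaded light dynamics in 3-D canopies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(canolux)
```

## The problem

A leaf surface deep inside a canopy does not see a smooth diurnal light
curve. As the sun moves, gaps between upper leaves open and close lines of
sight, so any small surface patch alternates between *sunlit* periods, when
it receives the full direct beam, and *shaded* periods, when the beam is
occluded and only diffuse light remains. These sunfleck dynamics drive
photosynthesis, photoprotection and photoinhibition, but resolving them by
ray tracing a full 3-D canopy reconstruction at minute resolution is
expensive and produces data too large and too detailed to reason about
directly.

canolux implements a parsimonious stochastic description of these dynamics:
a two-state (sunlit/shaded) process per patch whose switching rates depend
only on the time of day and on the patch's normalized height in the canopy.
Six parameters summarize an entire canopy's light dynamics; the model is fit
by maximum likelihood from extracted switching times and can be simulated in
milliseconds.

## From geometry to switching records

A canopy is a triangle mesh (`canopy_mesh()`, coordinates in mm, z up).
Each patch `j` has a centroid, a one-sided area, a unit normal (oriented
upward: leaves are treated as two-sided) and a normalized height

$$h_j = \frac{z_j - z_{\min}}{z_{\max} - z_{\min}} \in [0, 1],$$

where $z_{\min}, z_{\max}$ run over all vertices of the *assembled* canopy,
not per plant. The leaf area index (LAI) is total patch area over
ground-cell area; `cumulative_lai_profile()` accumulates it from the top
down. `tile_canopy()` assembles a single plant either into a periodic box
hugging its footprint or onto a 3x3 lattice with random per-copy rotations,
where the ground cell passes through the centres of the boundary plants and
the per-cell LAI is one plant's area per $d^2$.

The clear-sky direct-beam envelope on a patch with unit normal $n$ is

$$A_\mathrm{dr}(t) = S_0\,\tau^{1/\sin\alpha(t)}\,\lvert n \cdot
s(t)\rvert,$$

with $s(t)$ the unit sun direction from standard declination/hour-angle
geometry, $\alpha$ the solar elevation, $\tau$ the atmospheric
transmittance and $1/\sin\alpha$ the optical air mass. Time is solar time
in hours on a 12-h window starting at 0600, so $t_\mathrm{md} = 6$ h is
noon; defaults are latitude 53, day 182, $\tau = 0.5$. The constant $S_0$
(default 4600 umol m^-2^ s^-1^ PPFD) is calibrated so the noon horizontal
envelope is ~1800 umol m^-2^ s^-1^ under the defaults; it cancels in the
sunlit/shaded classification, which is relative. Diffuse light on a
horizontal surface uses a simple isotropic partition,
$0.3\,S_0(1-\tau^{1/\sin\alpha})\sin\alpha$.

`trace_canopy()` stands in for a ray tracer: a patch's direct flux at a
grid time is $A_\mathrm{dr}(t)$ if the straight line from its centroid to
the sun meets no other patch, else 0. Rays wrap at the vertical walls of
the ground cell (periodic boundary conditions), implemented by testing the
finitely many periodic images a climbing ray can reach below the canopy
top; the ray-triangle test is a compiled Moller-Trumbore kernel with a
1e-9 mm tolerance and self-intersection excluded by patch id. Leaves are
opaque; scattered and transmitted light are out of scope, and the 10%
classification margin absorbs small transmitted components.

A patch is classified sunlit at a grid time when its traced flux is within
10% (relative) of its envelope. Times at which the envelope falls below
1 umol m^-2^ s^-1^ are excluded: at the window edges these are pre-sunrise
or post-sunset points, and in the interior they occur when the beam grazes
the leaf plane, where the relative comparison is undefined; interior
unobservable points inherit the last observed state. Switch times are
placed at the grid point where the new state is first observed, making
classification -> extraction -> reconstruction exact at grid resolution.

A day is then a `switch_record()`: alternating on-times $x_i$ (shaded to
sunlit) and off-times $y_i$, with censored boundaries encoded by sentinels
($x_1 < 0$: sunlit at $t = 0$; $y_n > T$: sunlit at $t = T$; the sentinel
magnitudes, -1 and $T+1$, never enter any computation).

## The stochastic models

**Single-patch model.** Switching events form a non-homogeneous Poisson
process with quadratic intensity $\lambda(t;\theta) = \theta_1 + \theta_2 t
+ \theta_3 (t - t_\mathrm{md})^2$, cumulative intensity $\Lambda(t)$ in
closed (cubic) form, and log-likelihood $\ell(\theta) = -\Lambda(T) +
\sum_i \log\lambda(v_i)$. Because $\lambda$ is linear in $\theta$, $\ell$
is concave on the feasible region; `fit_model1()` maximizes it by
Nelder-Mead with a soft penalty where the intensity would become
non-positive (the penalty keeps the feasible region open and preserves
concavity inside it; a reparameterization would not).

**Two-state model.** The main model gives every patch at height $h$ two
rates,

$$\lambda^\mathrm{on}_h(t) = (1 - a_\mathrm{on} h)\,
  (b^\mathrm{on}_1 + b^\mathrm{on}_2 (t - t_\mathrm{md})^2), \qquad
\lambda^\mathrm{off}_h(t) = (1 - a_\mathrm{off} h)\,
  (b^\mathrm{off}_1 + b^\mathrm{off}_2 (t - t_\mathrm{md})^2),$$

linear in height, parabolic and noon-symmetric in time. $a_\mathrm{off} =
1$ is allowed: the off rate is then exactly zero at the canopy top, where
unobstructed patches never switch off. The on-rate must stay strictly
positive on $[0,1] \times [0,T]$ and the off-rate non-negative; linearity
means checking $h \in \{0, 1\}$ and $t \in \{0, t_\mathrm{md}, T\}$
suffices.

The log-likelihood is implemented by *interval bookkeeping* rather than by
transcribing per-event boundary formulas: each record decomposes into
maximal single-state intervals; every shaded interval contributes an
on-survival term $-\Delta\Lambda^\mathrm{on}_h$ plus, if it ends with an
interior switch, $\log\lambda^\mathrm{on}_h$ at the switch time (the off
likelihood mirrors this over sunlit intervals). This form reduces provably
to the per-event sums in the interior and handles all four censored
boundary configurations uniformly — in particular, a patch sunlit all day
contributes exactly 0 to the on-likelihood. The suite verifies it against a
brute-force Bernoulli-product discretization at $\delta t = 10^{-4}$ h.

The on-triple appears only in shaded exposure and the off-triple only in
sunlit exposure, so `fit_model2()` fits the two triples independently
(Nelder-Mead, soft positivity penalties, moment-matched constant-rate
starts, a restart polish, `reltol 1e-10`). Patches are pooled assuming
independence — spatial correlation between patches is deliberately not
modelled. The initial-state law $\Pr\{\text{sunlit at } t = 0\} = h$ is
used for simulation only, not as a likelihood factor: fitting conditions on
the observed initial states.

Simulation uses the inversion method: each holding time solves
$\Lambda(v + s) - \Lambda(v) = -\log(1 - U)$. The cumulative rates are
monotone cubics, so the solver is a fixed 60-step bisection (precision far
below 1e-8 h), vectorized in lockstep across patches, which makes
simulating thousands of patch-days essentially instant.

## Synthetic canopies: what they emulate and what they do not

`make_synthetic_canopy()` generates reproducible triangle-mesh fixtures:
stacked horizontal leaves (a worst-case occlusion column), a random rosette
(leaves radiating from a stem), uniformly scattered leaves (a homogeneous
closed canopy with directly controllable LAI), and a 3x3 lattice tiling.
Leaf sizes and height ranges default to rosette-plant magnitudes (order
100 mm leaves over a 50-600 mm height range); the scattered-leaf canopy
used in the acceptance experiments is sized to LAI ~ 3, matching the
denser reference canopies. These fixtures reproduce the *mechanism* the
model describes — solar-geometry-driven binary occlusion over a periodic
canopy — so a green test establishes that extraction, likelihood, fitting
and simulation are correct on exactly the kind of data the model assumes.
They do not reproduce real plant architecture: no curved or clumped
foliage, no stems, no scattered/transmitted radiance, no wind. Quantities
tied to a specific real canopy (e.g. a cross-source gain correlation of
0.92 reported for a ray-traced wheat reconstruction) are therefore checked
only as the analogous property on the synthetic stand-in (r > 0.8 at 1000
patches).

## Case study: photoinhibition

The light response is a non-rectangular hyperbola: $P(I)$ is the lower
root of $\theta P^2 - (\phi I + P_\max)P + \phi I P_\max = 0$, with
quantum yield $\phi$, convexity $\theta \in (0,1]$ and saturated rate
$P_\max$. Limits are handled explicitly: $\theta \to 0$ gives the
rectangular hyperbola (used below $\theta = 10^{-8}$) and $\theta = 1$
gives $\min(\phi I, P_\max)$. Layer capacities default to 28.6 / 12.6 /
4.7 umol m^-2^ s^-1^ for top/middle/bottom; layers are equal thirds of
normalized height (no numeric cutoffs being otherwise established). The
shared shape defaults $\phi = 0.062$, $\theta = 0.83$ are typical
field-measured wheat values and are exposed as configuration, documented
here as assumptions rather than constants of the method.

Diffuse light shares one diurnal shape across patches; each patch only
scales its amplitude. `fit_diffuse_scaling()` computes the closed-form
least-squares scalar per patch, clamps it to [0, 1], and summarizes scaling
versus height in 100 bins joined piecewise-linearly (a spline would add
smoothness assumptions without changing any conclusion). Daily carbon gain
integrates $P(\text{direct} \times \text{sunlit indicator} +
\text{diffuse})$ by trapezoid over the minute grid (plus the final step to
$T$), and averages gains — not light — over simulated realizations
(default 10), because $P$ is nonlinear. Photoinhibition is a multiplicative
scaling of $\phi$, $\theta$, or both (scenario `both`) by layer factors
0.857 / 0.955 / 1.0; reported reductions are
$1 - \text{gain}_\text{inhibited}/\text{gain}_\text{control}$ per layer
and in total. Since $P$ is non-decreasing in both $\phi$ and $\theta$, the
`both` scenario always dominates the single-parameter scenarios.

## Cross-canopy summaries

`canopy_param_table()` ships fitted parameters and LAI for 15 contrasting
reference canopies. `pca_params()` performs PCA on the correlation matrix
of the six parameters (LAI excluded; components signed so the dominant
loading is positive). On this table PC1 explains ~53% of the variance and
correlates with LAI at $|r| \approx 0.95$ — a "shadedness" axis. Note that
the bundled table stores the parameters rounded to at most a few
significant figures; summary statistics published for the same canopies
from unrounded estimates (59% explained, $|r| = 0.984$) are not exactly
reproducible from the rounded table, although the loadings agree to about
0.02. The eigenvalues and the correlation are simply more sensitive to the
rounding than the eigenvectors are.

```{r pca}
tab <- canopy_param_table()
pca <- pca_params(tab)
round(100 * pca$var_explained, 1)
pc_lai_correlation(pca, tab, 1)
```

## Numerical choices, in one place

* Intensities are validated on construction (fine grid for the quadratic
  model; exact vertex checks for the factorized rates).
* Inversion sampling: 60-step bisection on monotone cubics; if the
  cumulative rate to $T$ is below the exponential draw, the state persists
  to the window end.
* Optimization: Nelder-Mead, `reltol 1e-10`, `maxit 5000`, soft penalties
  (-1e10 scale) outside the feasible region, restart polish; model-1 fits
  add 3 seeded random restarts.
* Ray-triangle tolerance 1e-9 mm; periodic wrapping capped at the images
  reachable below $z_{\max}$, restricted to a band of cells around the
  projected ray.
* Degenerate inputs error early and explicitly: zero canopy height range,
  empty meshes, non-alternating switch times, all-censored fits, zero
  diffuse reference profiles.
* Single-time-step flickers are kept — no minimum sunfleck duration filter
  is applied.

## Known limitations

Binary light states (no partial shading within a patch); no spatial
correlation between patches and no heterogeneity among patches at the same
height (the model describes an average patch per height, so it never
predicts permanently dark patches, unlike ray-traced data); static canopy
(no wind); diffuse and scattered radiation enter only through the scaled
diffuse profile. The occlusion oracle tests centroids only, which is
adequate for small patches but not for coarse meshes.
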