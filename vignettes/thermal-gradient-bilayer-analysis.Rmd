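---
title: "Analyzing lipid bilayers under thermal gradients with thermolip"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analyzing lipid bilayers under thermal gradients with thermolip}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thermolip)
```

## The physical setting

Boundary-driven nonequilibrium molecular dynamics (NEMD) imposes a
stationary heat flux on a membrane system: water slabs at the edges of a
periodic box are held cold (300 K) and a slab at the center is held hot
(325-425 K), so heat flows symmetrically through two independent bilayers
stacked along z. In the stationary state the system exhibits

* a steady heat flux $J_q$ through the membrane, measured from the energy
  the thermostats inject and remove;
* a temperature profile $T(z)$ that is approximately linear across each
  bilayer;
* a slow redistribution of cholesterol between the hot-facing and
  cold-facing leaflets (phospholipids do not flip-flop on microsecond
  scales, cholesterol does).

`thermolip` implements the complete analysis of such runs — transport
coefficients, flip-flop kinetics, Soret coefficients, free-energy
landscapes and structural metrics — together with synthetic generators
that emulate each input with known ground truth, so every stage is
verifiable without running molecular dynamics.

## Heat transport

The thermostat energy ledger records cumulative energies $E_{hot}(t)$,
$E_{cold}(t)$. The energy rate is a least-squares slope over the
steady-state window (by default everything after the first 100 ns, the
time scale on which these systems become stationary); the hot and cold
rates are cross-checked and averaged, and the flux is

$$J_q = \frac{dE/dt}{2\,A},$$

with the factor 2 because the periodic two-bilayer geometry gives the
hot slab two heat paths (configurable to 1). Fourier's law and the
interfacial conductance follow:

$$J_q = -\lambda \nabla T, \qquad G = \lambda / \delta,$$

where $\nabla T$ is the regression slope of the binned temperature
profile over the membrane window (auto-detected as the region between the
two phosphate density maxima, overridable) and $\delta$ is the mean
separation of the phosphate headgroup planes. Internally everything is in
MD units (nm, ps, K, kJ/mol, amu); conversion to W and m happens once, at
the reporting boundary. Sign convention: $\nabla T$ is $dT/dz$ across the
analyzed bilayer and $J_q$ the flux along $+z$, so $\lambda$ is positive
whenever heat flows hot to cold; a negative $\lambda$ flags inconsistent
inputs rather than being reported as a result.

```{r transport}
g <- gen_ledger(lambda_target = 0.124, gradT = -2e9, area = 36)
lam <- conductivity(heat_flux(g$ledger), fit_gradient(g$profile, g$window))
lam$lambda
```

The generator inverts the analysis exactly, so the noiseless round trip
recovers the target conductivity to full precision; with 5% noise on the
ledger increments and on the profile the median recovery over 100 seeds
stays within 2%.

## Temperature and density profiles

Profiles are binned on the fractional coordinate $z/L_z$ (so
constant-pressure box fluctuations do not smear bins), with half-open
bins. The kinetic temperature per bin is

$$T = \frac{\sum_i m_i |v_i - u|^2}{3 N k_B},$$

with $u$ the bin's mass-weighted streaming velocity (subtracted by
default — it removes advective bias near the thermostats and makes the
estimator invariant under a global velocity boost). Coarse-grained beads
carry 3 translational degrees of freedom and no constraint corrections.
$k_B = 0.0083144621$ kJ/(mol K). The Maxwell-Boltzmann generator draws
per-component velocities with variance $k_B T(z)/m$, which in these units
is directly (nm/ps)$^2$; the stationary NEMD state is locally Maxwellian
to leading order, which is exactly what it emulates (no cross-bin
velocity correlations, no hydrodynamic modes).

## Flip-flop kinetics and the Soret coefficient

Cholesterol is assigned to leaflets by its hydroxyl (ROH) bead against
the bilayer midplane, defined as the mean phosphate z — a definition
robust to the cholesterol asymmetry being measured. A molecule exactly at
the midplane keeps its previous label (hysteresis tie rule; first frame
goes to the cold leaflet), so jitter at the midplane does not generate
spurious crossings and $x_{cold}(t) + x_{hot}(t) = 1$ always.

The fraction of cholesterol in the cold leaflet relaxes as a two-state
process:

$$x(t) = x(0) + \left(x^s - x(0)\right)\left(1 - e^{-t/\tau}\right),
\qquad \tau^{-1} = k_{ch} + k_{hc},$$

fitted by nonlinear least squares with $x(0)$ fixed at 0.5 (all study
systems start symmetric; a free-$x(0)$ mode exists). Initialization uses
the mean of the final 20% for $x^s$ and the $1-1/e$ crossing time for
$\tau$. A constant series is flagged degenerate ($\tau$ unidentifiable)
rather than fitted. The steady asymmetry is $\Delta x = x^s - x(0)$, and
the finite-difference Soret coefficient is

$$S_T = -\frac{1}{x^o_{CHOL}\, x^o_{PC}}\,
        \frac{\Delta x'_{CHOL}}{\Delta T},$$

with $x'_{CHOL,\alpha} = N_{CHOL,\alpha}/(N_{CHOL,\alpha}+N_{PC,\alpha})$
the steady-state per-leaflet mole fractions (counted over $t > 5\tau$,
falling back with a warning to the final 20% of a short series) and
$\Delta T$ the leaflet temperature difference, read off the fitted
profile at the phosphate peak positions. Positive $S_T$ means cold-side
enrichment: a thermophobic solute.

```{r kinetics}
s <- gen_kinetic_series(x0 = 0.5, xs = 0.56, tau = 16.1)
fit_kinetics(s)
```

## Free-energy landscapes

For each cholesterol the package records the hydroxyl height $z$ relative
to the midplane and the tilt angle $\theta$ between the molecular
director (terminal tail bead to hydroxyl) and the *outward normal of the
leaflet holding the hydroxyl*. This leaflet-relative convention makes
canonically upright cholesterol score small $\theta$ in both leaflets and
inverted configurations score near $180°$, so the landscape shows the
upright states of the two leaflets and the inverted metastable states as
distinct minima; a fixed $+z$ axis mode is available. The surface is

$$F(z, \theta) = -\ln\frac{P(z,\theta)}{P_{ref}}, \qquad
  P_{ref} = \max_{z,\theta} P,$$

a map of raw populations (no $\sin\theta$ Jacobian — the quantity is the
population of states, and the local $k_B T(z)$ scaling is implicit in
$-\ln P$, with no rescaling between leaflets). Zero-count bins are
masked; the display ceiling (default 10) applies at export only. Default
bins are 0.1 nm by 2°, fine enough to resolve the ~13° vs ~20°
separation of the two upright states. One-dimensional projections take,
for each value of the kept coordinate, the minimum of $F$ over the other
one — the lowest free-energy cost of the most favorable configuration.

Minima are unmasked bins lower than their 8-neighborhood (exact ties
break lexicographically, so a minimum spanning two equal bins is counted
once), filtered by topographic prominence (persistence) $\geq 0.5$ and by
a statistical-support floor: a minimum must sit in a bin with at least
100 samples, because the noise of $-\ln P$ in a bin with $c$ counts is
$\approx 1/\sqrt{c}$ and the prominence threshold should be several times
the noise. Labels follow the five canonical states: upright cold/hot
(A/B), midplane in-plane (C, $|z| < 0.5$ nm), inverted cold/hot (D/E);
anything else becomes X1, X2, ...

The generator side draws $(z,\theta)$ samples bin-wise proportional to
$e^{-F}$ with uniform jitter inside each bin, so histogram reconstruction
is the exact inverse and the round trip is an identity up to multinomial
noise.

## The Langevin thermophoresis stand-in

Cholesterol translocation under a gradient is emulated at desk scale by
an overdamped Langevin particle in a double well
$F(z) = h\,[(z/z_w)^2 - 1]^2$ (default $h = 2.5\,k_BT$, $z_w = 1$ nm)
with position-dependent temperature, using the Ito Euler-Maruyama update

$$z \leftarrow z - \frac{F'(z)}{\gamma}\Delta t +
  \sqrt{\frac{2 k_B T(z) \Delta t}{\gamma}}\,\xi.$$

The Ito convention is fixed deliberately: it determines the stationary
density $p(z) \propto T(z)^{-1} \exp\left(-\int F'/k_BT\,dz\right)$
against which the simulator is checked. With symmetric wells and a hotter
upper side both the $1/T$ prefactor and the barrier integral deplete the
hot well — thermophobic partitioning emerges from the dynamics rather
than being put in, and its magnitude is linear in $\Delta T$ for small
gradients. The tilt coordinate is an independent Ornstein-Uhlenbeck angle
around a leaflet-dependent mean; it exercises the landscape machinery but
carries no physical claim — only the z dynamics embody thermophoresis.

Numerical safeguards: a mandatory seed; a stability check requiring the
drift step $\Delta t\,\max|F'|/\gamma$ to stay under 5% of the domain and
$\Delta t\,\max|F''|/\gamma < 0.5$, both evaluated over the thermally
accessible region ($F$ within 15 $k_BT$ of its minimum — the potential at
the hard domain walls is never visited); divergence beyond the domain is
an error naming the step. Well-to-well crossings are counted with a
commitment threshold (default 0.5 nm past the boundary), so diffusive
jitter at the barrier top is not counted as flip-flop. Friction is
expressed as $\gamma$ in kJ/mol ps/nm² ($D = k_BT/\gamma$; the default
$\gamma = 5$ gives $D \approx 0.5$ nm²/ps, fast enough that a $10^6$-step
run crosses the barrier thousands of times). Occupancy statistics use
every step; the returned trajectory is thinned by a stride.

For the linear-response check the four gradient runs share one RNG seed
(common random numbers): the sampling noise is then common mode and
cancels from the response curve, which is what lets four $10^6$-step runs
resolve the linearity cleanly. With 64 particles the occupancy standard
error per run is about 0.003.

## Structure metrics and melting

The chain order parameter is $S = \langle (3\cos^2\beta - 1)/2 \rangle$
over consecutive tail-bead bonds against $+z$ (1 aligned, 0 isotropic,
−0.5 in-plane). The area per PC molecule is $L_x L_y / N_{PC,leaflet}$ —
cholesterol is deliberately excluded from the denominator. Lateral RDFs
use minimum-image $(x,y)$ distances within one leaflet, normalized by the
ideal-gas annulus density.

Melting temperatures come from annealing hysteresis cycles: per
direction, the transition temperature is the peak of the smoothed
derivative $|dv/dT|$ (moving average over 5 temperature points, parabolic
sub-grid refinement; fallback to the mid-level crossing), and
$T_m = (T_{m,heat} + T_{m,cool})/2$. The midpoint rule is an estimator
choice — flagged in the result metadata — made because the annealing
literature motivates the construction but does not pin down a unique
estimator; on noiseless sigmoids it recovers the analytic midpoints
exactly, and the parabolic refinement leaves a symmetric peak untouched.
A scan whose relief does not exceed several times its own noise scale
reports "no transition detected" — the behavior expected of a bilayer
whose transition lies outside the scanned interval.

## Synthetic study conditions and their limits

The generators' defaults are the study conditions used throughout the
tests and the analysis scripts: conductivity target 0.124 W/(K m) with a
gradient of $2\times10^9$ K/m across a 4 nm window; kinetic series with
$\tau = 16.1$ ns and $x^s = 0.56$ from a symmetric start; a 50:50
PC:cholesterol schematic membrane (100 PC per leaflet at 0.64 nm², 4 nm
phosphate separation, half-normal chain tilt of 20° giving
$S_{chain} \approx 0.84$, cholesterol tilt 10°); hysteresis scans between
gel (0.478 nm²) and fluid (0.634 nm²) areas over 280-340 K with
midpoints 310/303 K; five-well landscape with minima at
$(z,\theta) = (\pm1.45, 13/21°)$, $(0.05, 91°)$ and $(\pm0.65, 159°)$.
Noise models the reference protocol leaves unspecified were fixed once:
relative Gaussian noise on ledger increments, additive profile noise
scaled to the temperature span, i.i.d. Gaussian noise on fraction series,
and a 0.02 occupancy jitter for replica scatter.

Passing these tests shows the estimators invert their generating models
at realistic sizes and noise levels. It does not show force-field realism:
the schematic membrane has no packing correlations, no undulations, no
interdigitation, and its cholesterol occupancy follows an imposed
schedule rather than emerging from energetics; the Langevin model is
one-dimensional. Those are properties of real NEMD data the pipeline
consumes, not of the generators.

Problem sizes in the default test and analysis runs — $10^5$ beads for
profile checks, $10^6$ landscape samples, $10^6$-step Langevin runs,
5 replicas of 35-frame trajectories — were chosen so each stage's
statistical error sits well inside its tolerance.

## Design notes

* Trajectories are multi-frame GRO text (concatenated models with `t=`
  stamps, as MD engines emit); streaming and eager reads are equivalent
  by construction and by test. Orthorhombic boxes only — the slab
  geometry is orthorhombic, and triclinic input is an explicit error.
* Bead indices are 1-based throughout, matching both R convention and the
  1-based serials of coordinate files, so the file round trip is the
  identity on indices.
* Ledgers store cumulative energy, never instantaneous power; rates are
  recovered by regression, which is robust to uneven sampling.
* Uncertainties across replicas are standard errors of the mean;
  single-replica results report the SEM as unavailable rather than zero.
* The data model is stride-agnostic: no analysis assumes uniform frame
  spacing.

## Known limitations

Two-bilayer stacks are handled by per-bilayer windows
(`bilayer_range`) rather than a first-class multi-bilayer container;
per-leaflet lateral heterogeneity maps, Green-Kubo conductivities,
transition rates from the landscape, and water permeability are out of
scope. The tilt-angle director uses the terminal tail bead; for real
coarse-grained cholesterol topologies the bead choice should be checked
against the model's geometry.
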