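---
title: "Cell-model thermodynamics and competing-interaction Monte Carlo for crowded DNA brushes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cell-model thermodynamics and competing-interaction Monte Carlo for crowded DNA brushes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(brushpack)
```

# The system and the questions

A spherical polyelectrolyte brush (SPB) is a colloidal core densely grafted
with charged polymer chains — here a polystyrene bead of radius
$R_\mathrm{PS} = 0.49\,\mu m$ carrying $f \approx 10^5$ double-stranded DNA
fragments of 10 kbp (contour length $L_C = 3.4\,\mu m$).  In salt-free water
such brushes are *osmotic*: nearly all counterions stay inside the brush, the
chains stretch almost fully, and the particle behaves as a soft sphere of
dilute diameter $\sigma_0 = 2(R_\mathrm{PS} + L_C)$.  `brushpack` addresses
two linked questions about quasi-2D dispersions of these particles:

1. **How does crowding change the single-particle size and the counterion
   partition?**  Answered by a Wigner–Seitz cell model whose free energy is
   minimized over the brush thickness $L$ and the number of escaped
   counterions $N_3$.
2. **What collective structures emerge when a weak short-range attraction
   (blunt-end stacking between stretched dsDNA termini of touching brushes)
   competes with residual electrostatic repulsion?**  Answered by 2D
   Metropolis Monte Carlo of disks with a steep 100–200 Lennard-Jones
   attraction plus a repulsive Yukawa tail, followed by structural
   ($g(r)$, $\Psi_6$, neighbour statistics) and dynamical (MSD, $D_\mathrm{eff}$)
   analysis.

# The cell model

One SPB sits at the centre of a spherical Wigner–Seitz cell of radius
$R_W$, fixed by the packing fraction through the 3D convention
$\eta = R_0^3 / R_W^3$ with $R_0 = R_\mathrm{PS} + L_C$.  (The experiment
reports a 2D area fraction; retaining the 3D mapping is a deliberate
modelling convention, documented here, so that dilution limits behave
correctly.)  Each chain carries $N$ elementary charges at spacing $b$;
for dsDNA we take $b = 0.17$ nm (two charges per 0.34 nm base-pair rise),
which makes $N = L_C/b = 2\times10^4$ and $N f \approx 2\times10^9$
counterions per particle.

Counterions split into three populations: $N_1$ condensed on the chains,
$N_2$ mobile inside the brush, $N_3$ escaped into the outer shell, with
charge neutrality $N_1 + N_2 + N_3 = N f$ holding identically.  Manning
condensation fixes $N_1 = N f\,(1 - 1/\xi)$ for $\xi = \lambda_B/b > 1$,
i.e. condensation proceeds until one net charge per Bjerrum length
$\lambda_B = e^2 / (4\pi \varepsilon k_B T)$ remains ($\lambda_B \approx
0.71$ nm in water at 298 K, so $\xi \approx 4.2$ for dsDNA).  $N_1$ is kept
continuous during minimization for smoothness.

The variational free energy $F(L, N_3)$ sums six contributions, all in
$k_B T$:

* **Hartree electrostatics** $U_H = \tfrac{1}{2}\int\!\!\int
  \rho(r)\rho(r')/(4\pi\varepsilon|\mathbf r - \mathbf r'|)$, evaluated for
  the mean-field charge profile: stretched chains give a charged-monomer
  density $\propto r^{-2}$ through the brush, the absorbed counterions track
  it, so the brush shell carries net charge $-eN_3$ with an $r^{-2}$
  profile and the outer shell carries $+eN_3$ homogeneously.  By spherical
  symmetry $U_H = (\lambda_B/2)\int q(r)^2/r^2\,dr$ with $q(r)$ the enclosed
  charge; the package evaluates the piecewise-analytic antiderivatives and
  cross-checks them against adaptive quadrature (tested to $10^{-8}$
  relative, and against the uniform-sphere closed form
  $\tfrac{3}{5}Q^2/(4\pi\varepsilon R)$ to 0.1 %).
* **Chain elasticity** $F_\mathrm{el} = \tfrac{3}{2} f L^2/(N b^2)$ —
  Gaussian stretching entropy of $f$ chains.
* **Flory excluded volume** $F_\mathrm{Fl} = \tfrac{1}{2} v (N f)^2 /
  V_\mathrm{brush}$ with $v = \tfrac{4}{3}\pi R_m^3$ the volume of one
  monomer and $V_\mathrm{brush}$ the spherical-shell volume between
  $R_\mathrm{PS}$ and $R = R_\mathrm{PS} + L$.
* **Counterion entropies** $-TS_i = \int n_i\,[\ln(n_i d^3) - 1]\,dV$ for
  the inside ($i = 2$, $r^{-2}$ profile) and outside ($i = 3$, homogeneous)
  populations, $d$ the counterion diameter.  Inside the brush the chain
  monomers reduce the accessible volume, implemented as
  $n_2 \to n_2/\phi_\mathrm{free}$ with $\phi_\mathrm{free} = 1 - v N f /
  V_\mathrm{brush}$; states with $\phi_\mathrm{free} \le 0$ are rejected as
  unphysical.  The de Broglie length-scale constant is omitted (it shifts
  $F$ by a constant).
* **Osmotic insertion** $F_p = N_2 (R/R_W)^3$: the cost of inserting a brush
  of radius $R$ into the suspension of its neighbours, the expelled volume
  $\sim R^3$ times the osmotic pressure $\Pi(R_W) \sim N_2 k_B T/R_W^3$ of
  their trapped counterions.  The $\tfrac{4}{3}\pi$ factors of the expelled
  volume and the cell volume cancel, so the prefactor is 1.  The estimate is
  meaningful in the osmotic regime $N_2 \gg N_3$; the implementation flags
  states violating it.

## Numerical minimization

$N_3$ spans many decades (from $O(10)$ at strong trapping to $O(10^8)$),
so the landscape is smooth but very anisotropic.  The minimizer uses a
coarse scan — 48 linear points in $L$ over $[0.05 L_C,\ \min(L_C, R_W -
R_\mathrm{PS})]$ times 48 logarithmic points in $N_3$ plus the $N_3 = 0$
edge — followed by a nested 1D polish: golden-section over $\log N_3$ at
fixed $L$ inside golden-section over $L$, to $10^{-6}$ relative in the
total.  The lower bound $0.05 L_C$ keeps the Flory and entropy terms
finite; the reported equilibria sit far from it.  Optimality is verified in
the tests against the 8 surrounding points of a local perturbation stencil.
A plain Nelder–Mead polish in $(L, \log N_3)$ was tried first and found to
drift along the shallow $N_3$ valley; the nested profile search is the
design answer to that anisotropy.

Two parameters have no measured values and are exposed with defaults:
monomer radius $R_m = 1$ nm and counterion diameter $d = 0.7$ nm (hydrated
monovalent ion).  Both enter logarithmically or through slowly varying
terms; the headline outputs (release fraction order, relative shrinking)
are insensitive to factor-of-two changes.

With the experimental geometry and a dilute cell ($R_W = 10 R_0$) the model
releases a fraction $\sim 2\times10^{-5}$ of the counterions and predicts a
dilute diameter about 41 % below $\sigma_0$ — the expected accuracy class of
a scaling theory, whose value lies in trends: release falls with $f$, rises
with $R_W$, and $\sigma(\eta)$ decreases monotonically with packing.

## The diameter fed to the simulations

The simulations need the steric diameter $\sigma(\eta)$.  Two sources are
provided:

* `experimental_sigma_table()` (default for the six canonical state
  points): the measured first-peak positions $r_p/\sigma_0$ of $g(r)$,
  which track the actual particle shrinking (values 0.88, 0.89, 0.82,
  0.70, 0.73, 0.78 at $\eta$ = 0.40 … 1.17; approximate readings of the
  reported trend).
* `sigma_of_eta()`: the cell-model curve rescaled to $\sigma(\eta \to 0) =
  \sigma_0$.

The default is the measured table because the cell model, while monotone,
under-predicts the *depth* of the shrinking (it reaches only $\sim$4–12 %
by $\eta = 1.17$).  With the theory curve the densest state point would
demand an effective area fraction $\eta\,(\sigma/\sigma_0)^2 \approx 1.08$,
beyond the hexagonal close-packing bound 0.9069 — geometrically impossible
for near-hard disks.  This mirrors how the simulations were designed to be
driven by the measured sizes in the first place; the theory mapping remains
available for sensitivity studies and is the main acknowledged source of
quantitative deviation.

# The Monte Carlo engine

Disks interact through

$$ V(r) = 4V_1\left[\left(\frac{\sigma}{r}\right)^{200} -
\left(\frac{\sigma}{r}\right)^{100}\right] +
V_2\,\frac{e^{-r/\lambda}}{r/\lambda}, \qquad r < r_c = 3.5\,\sigma $$

with defaults $V_1 = 1.43\,k_BT$, $V_2 = 0.28\,k_BT$, $\lambda = 1.5\,
\sigma_0$.  The steep 100–200 core forbids interdigitation (brush overlaps
cost energies set by the $\sim 10^9$ absorbed counterions), the narrow well
just beyond $r = \sigma$ models blunt-end stacking, and the Yukawa tail the
weak residual repulsion of nearly neutral brushes.  Because the printed
normalization of such potentials varies, both conventions are implemented
behind `lj_convention`: `"4v1"` (default; Mie-type prefactor, zero crossing
at $\sigma$, well depth $V_1$ at $r = 2^{1/100}\sigma$) and `"well"`
($V_1[(\sigma/r)^{200} - 2(\sigma/r)^{100}]$, depth $V_1$ at $\sigma$).
The potential is truncated, not shifted, at $r_c$; in 2D with these ranges
tail corrections are negligible for structure.

Choices the engine fixes (and why):

* **Periodic boundaries with minimum image** in the $20\sigma_0 \times
  20\sigma_0$ box — the standard bulk-phase setup.
* **Particle counts** $N = \{196, 289, 342, 380, 441, 600\}$ at $\eta =
  \{0.40, 0.57, 0.68, 0.73, 0.87, 1.17\}$ ($\eta = n\pi\sigma_0^2/4$
  recomputes the tabulated values to two decimals); non-tabulated $\eta$
  fall back to the area-fraction formula.
* **Initialization**: random sequential insertion with overlap rejection at
  $0.95\sigma$, falling back to a diluted triangular lattice above
  $\eta = 0.8$ or when insertion stalls.
* **Move amplitude** auto-tuned during equilibration toward 30–50 %
  acceptance, then frozen for production; the first 30 % of each run (within
  the 20–50 % equilibration window) is discarded.
* **Determinism**: the compiled sweep loop draws from R's RNG, so
  `set.seed()` makes trajectories bit-reproducible; the test suite asserts
  this, and audits the incremental energy bookkeeping against a fresh
  $O(N^2)$ recomputation ($10^{-8}$ relative after 100 sweeps).

The compiled core (Rcpp) uses a linked-cell neighbour list, $O(1)$ per
trial move, which is what makes $10^4$–$10^5$ sweeps per state point
practical on one CPU.

# Structural analysis

$g(r) = N(r)/(2\pi n r \Delta r)$ per central particle, averaged over
configurations; default $\Delta r = 0.02\,\sigma_0$ (fine enough to
localize the contact peak, coarse enough for acceptable counting noise at
the snapshot counts used).  Periodic data use minimum-image distances;
open, experimental-style data use a guard region of width $r_\mathrm{max}$
— only interior particles act as centres — which is unbiased without
pair-count corrections.

The first peak $(r_p, g_p)$ is the first raw local maximum above 1 with
parabolic sub-bin refinement.  The neighbour rule is
$r_\mathrm{cut} = \sigma + (r_\mathrm{min} - r_\mathrm{max})/2$ with
$r_\mathrm{max}, r_\mathrm{min}$ the first-peak and first-minimum
positions; $\sigma$ is the $\eta$-dependent steric diameter (an override
argument exists).  Locating the first *minimum* on a noisy histogram needs
care: the implementation bounds the search window by the next peak of a
5-bin-smoothed curve that clears a prominence threshold
($0.1\,(g_p - 1)$, floor 0.05), then takes the raw minimum inside the
window.  Without the prominence guard, shoulder noise right after the
contact peak produces spurious minima and absurdly small cutoffs.

$\Psi_6^i = \bigl|\tfrac{1}{N_b}\sum_j e^{i6\theta_{ij}}\bigr|$ over the
neighbours of particle $i$; $\langle\Psi_6\rangle$ averages the
per-particle magnitudes (matching per-particle order maps; the modulus of
the complex mean is available via `combine = "complex"`).  Zero-neighbour
particles score 0; note that one- and two-neighbour particles score high
magnitudes by construction, which is why chain-dominated states can carry
sizeable $\langle\Psi_6\rangle$.  A perfect triangular lattice scores 1,
a square lattice exactly 0.

# Dynamics

Tracks (`frame,id,x,y`, default 15 fps) are dedrifted by subtracting the
accumulated frame-to-frame ensemble mean displacement of co-tracked
particles (a robust median option exists).  This removes any rigid stage
motion exactly — uniform or sinusoidal — at the cost of a $1/N$
ensemble-subtraction bias that the tests bound explicitly.  Frames sharing
fewer than two particles inherit the neighbouring drift estimate with a
warning.  The exact dedrifting filter used by tracking software is
tool-internal; this estimator is the package's documented stand-in.

The MSD is time- and ensemble-averaged over all valid origin pairs at every
integer frame lag, by default up to a quarter of the track length (longer
lags average too few, strongly correlated pairs).
$D_\mathrm{eff} = \mathrm{MSD}(\Delta t)/(4\Delta t)$ at the available lag
closest to the reference $\Delta t \approx 55$ s, with the offset reported.

# Synthetic references

The generators produce the structures each analysis is validated against:
triangular lattices ($\Psi_6 = 1$, peak ratios $1:\sqrt3:2$), square
lattices ($\Psi_6 = 0$), Poisson gases ($g \equiv 1$, low $\Psi_6$),
chainlike aggregates (self-avoiding strings at the bond distance with
gently curved backbones, bond-angle steps within $\pm30^\circ$; geometric
length distribution of mean 5 plus 20 % singles by default, emulating a
broad chain-length mix with isolated particles and mean coordination near
2), and 2D Brownian tracks with per-step variance $2D\,\Delta t$ per axis
plus optional drift.  All are seed-deterministic and box-respecting.

What they deliberately do **not** emulate: localization noise beyond
optional jitter, polydispersity, hydrodynamic correlations, out-of-plane
motion, or image-processing artefacts.  Passing the synthetic oracles
therefore validates the estimators, not the microscopy pipeline.

# Problem sizes in the shipped tests

The test suite runs the six state points at $2\times10^4$–$6\times10^4$
sweeps (the full-length prescription is $10^5$–$2\times10^6$), which keeps
the whole suite at a few minutes on one CPU while leaving the re-entrance
signature — non-monotone $g_p$ and $\langle\Psi_6\rangle$ with a dip
between $\eta = 0.7$ and $0.9$, chain-dominated coordination near 2 at
$\eta = 0.40$ — clearly resolved.  Diffusion recovery uses ensembles of
100–200 tracks of 250–300 frames over 8–10 seeds.  These sizes are the
package's chosen trade-off between statistical resolution and runtime.

# Known limitations

* The cell model is a scaling theory: absolute sizes carry $O(40\%)$ error
  by construction; only trends and orders of magnitude are quantitative.
* No added-salt term in the free energy; salt effects (screening-induced
  backfolding that switches off the blunt-end attraction) are outside the
  model.
* The release-fraction-vs-$R_W$ trend inverts below $R_W \approx 4 R_0$,
  where the insertion term dominates; the documented monotone behaviour
  refers to the dilution regime beyond that.
* $\langle\Psi_6\rangle$ comparisons across packings inherit the
  neighbour-cutoff rule; at chain-dominated states the measure is inflated
  by low-coordination particles (a property of the definition, shared by
  the per-particle-magnitude convention).
* The Monte Carlo treats $\sigma(\eta)$ as an input; it does not couple the
  cell model self-consistently to the local density of an aggregate.

```{r example, eval = FALSE}
# the headline cell-model numbers
geom <- experimental_brush_params()
eq <- minimize_free_energy(geom, R_W = 10 * (geom$R_PS + geom$L_C))
eq$release_fraction                    # ~2e-5: nearly all counterions trapped
2 * (geom$R_PS + eq$L_star) / 1000     # dilute diameter, um

# one reduced state point and its order metrics
tr <- run_state_point(0.73, config = sim_config(seed = 1, n_steps = 2e4))
order_metrics(tr$snapshots, sigma = tr$sigma)
```
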