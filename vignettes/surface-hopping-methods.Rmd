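---
title: "Surface hopping on the eigenstates of the total electronic Hamiltonian"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Surface hopping on the eigenstates of the total electronic Hamiltonian}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hopdyn)
```

## The model

Fewest-switches surface hopping propagates classical nuclei on one *active*
potential-energy surface at a time, while a quantum amplitude vector
$c(t)$ evolves under the electronic Schrödinger equation
$\dot c_\beta = -\sum_\alpha (i H_{\beta\alpha} + T_{\beta\alpha})
c_\alpha$, with $T = v\cdot K$ the time-derivative coupling. Stochastic
hops between surfaces are drawn so that, over an ensemble, the fraction of
trajectories on each surface follows the quantum populations.

The distinguishing choice in this package is the *representation*: the
nuclei move on the eigenstates of the **total** electronic Hamiltonian
$H^{\rm total} = H^{\rm spin\text{-}free} + H^{\rm SOC} - \mu\cdot E(t)$,
obtained by diagonalizing the matrix of $H^{\rm total}$ in a small basis of
spin-free (MCH) states, $H^{\rm diag} = U^\dagger H^{\rm MCH} U$. In this
*diagonal* representation spin–orbit and light–matter couplings deform the
surfaces and appear as localized avoided crossings, which is what a
fewest-switches algorithm handles well; in the spin-free representation the
same couplings would be wide and delocalized. The cost is a set of basis
transformations in every working equation:

* amplitudes are propagated by the **three-step propagator**
  $c^{\rm diag}(t+\Delta t) = U^\dagger(t+\Delta t)\, P^{\rm MCH}\,
  U(t)\, c^{\rm diag}(t)$, so the arbitrary phases of numerically computed
  eigenvectors cancel;
* the active-surface gradient is assembled from the spin-free gradients,
  $g_\alpha^{\rm diag} = \sum_\mu |U_{\mu\alpha}|^2 g_\mu +
  \sum_{\mu\neq\nu} U^*_{\mu\alpha}U_{\nu\alpha}
  (H_{\nu\nu}-H_{\mu\mu})K_{\mu\nu}$ — the second term is the off-diagonal
  derivative of the spin-free Hamiltonian expressed through the coupling
  vectors $K_{\mu\nu}=\langle\mu|\partial_R|\nu\rangle$ (we verified this
  sign convention against finite differences of the eigenvalues; with the
  opposite convention the conservation error doubles instead of
  vanishing). Hellmann–Feynman terms of the *additional* couplings
  (geometry derivatives of SOC or field terms) are omitted — a documented
  limitation relevant only for strong fields or dissociating heavy atoms;
* hopping probabilities use the propagator-based fewest-switches formula
  $h_{\beta\to\alpha} = \big(1 - \tfrac{|c_\beta'|^2}{|c_\beta|^2}\big)\,
  \Re[c_\alpha' P^*_{\alpha\beta} c^*_\beta]\,/\,
  \big(|c_\beta|^2 - \Re[c_\beta' P^*_{\beta\beta} c^*_\beta]\big)$,
  whose off-diagonal sum equals the fractional active-population loss
  exactly when $c' = P c$ (a unitarity identity the tests verify to
  1e-10). Negative entries are clamped to zero. The global-flux formula is
  available as an alternative.

## Electronic-structure surrogates

All electronic quantities come from analytical vibronic models
([vibronic_model()], [lvc_model()]): harmonic diagonal diabats with linear
intrastate ($\kappa$) and interstate ($\lambda$) couplings in dimensionless
mass-frequency-weighted coordinates (mode mass $1/\omega_i$), a constant
complex Hermitian coupling block holding SOC (triplets are expanded into
explicit MS components — merged "effective SOC" multiplets are known to
misbehave), and constant dipole matrices. A model evaluation mimics one
quantum-chemistry call: blockwise diagonalization of the spin-free diabatic
matrix gives energies, Hellmann–Feynman gradients, analytic coupling
vectors $K_{\mu\nu} = w_\mu^T(\partial V)w_\nu/(E_\nu-E_\mu)$, the overlap
matrix with the previous geometry, and transformed dipoles. Spin-free gaps
below `nac_threshold` (1e-8 hartree) zero the coupling element instead of
diverging; the overlap-based propagation is the supported route through
such crossings.

Two special models are bundled. `lz_model()` (linear diabats $\pm a x$,
constant coupling $b$, gap $2b$) validates the hopping machinery against
the closed-form single-passage probability
$P = \exp[-2\pi b^2/(2 a v)]$, with $v$ the velocity *at the crossing*
computed from energy conservation. `degenerate_crossing_model()` realises
the canonical phase-tracking stress test: a populated harmonic oscillator
sharing a spin-free group with four *exactly degenerate*, fully uncoupled
flat states, plus a second oscillator coupled to the first through the
constant coupling block so the transformation matrix is nontrivial. When
the oscillator sweeps through the multiplet, the energy-ordered spin-free
states relabel within a single time step — a simultaneous multi-state
trivial crossing.

## Phase tracking

Numerical eigenvectors carry arbitrary column phases and arbitrary
rotations within degenerate blocks. The tracked transformation
$U_{\rm tracked} = U_{\rm raw}[\hat O\hat C(U^\dagger_{\rm prev} S\,
U_{\rm raw})]^\dagger$ re-anchors each step's raw eigenvectors on the
previous step, with the spin-free overlap matrix $S$ transporting the old
frame across any relabeling first. $\hat C$ zeroes elements between
different degeneracy groups of the new spectrum (threshold 1e-9 hartree,
computed from the *new* step, consistent with requiring commutation with
the new diagonal Hamiltonian) and $\hat O$ is a blockwise Löwdin
orthonormalization via the SVD polar factor, stable for near-singular
blocks. Tracking therefore only re-phases and re-mixes within degenerate
blocks — the result always still diagonalizes the Hamiltonian.

At a genuine crossing stepped over in one $\Delta t$, the projected block
is structurally rank-deficient for the crossing partners: their phase link
across the step is genuinely lost. The standalone `track_phases()` treats
this as an error (the conservative contract: reduce the time step); the
dynamics driver instead completes the dead directions with the SVD unitary
(identity for fully dead blocks), records the event, and continues — this
is precisely the situation the overlap correction is for, and the
populations are routed correctly by the propagator regardless of the lost
phase. The projection-only variant (`tracking = "projection"`, kept for
comparison) matches states index-blindly and demonstrably ties phases and
degenerate-block assignments to the wrong states at simultaneous
crossings; the test suite shows a distinctly populated flat state being
handed a wrong label there, while the overlap algorithm leaves it
untouched to 1e-6.

## The integration loop

Each nuclear step is a velocity-Verlet cycle in kick–drift–kick form:
half-kick with the active gradient, drift, electronic work at the new
geometry (evaluation, sign fixing from the overlap matrix,
diagonalization, tracking, three-step propagation), then the hop test, and
finally the closing half-kick with the — possibly new — active state's
gradient. The hop rescales the *half-kicked* velocity, so
$E_{\rm kin}+E_{\rm active}$ is conserved exactly (to 1e-10) at the
rescaling instant; rescaling is along the transformed coupling vector
(falling back to the full velocity when it vanishes) or the full velocity
vector, frustrated hops keep the state and optionally reflect the parallel
velocity component, and while a laser field is on, hops whose gap matches
the photon energy within a tolerance (default twice the pulse's spectral
width) are accepted without mechanical rescaling, since the energy came
from the field. The energy-based decoherence correction
($\tau_\alpha^{-1} = |E_\alpha - E_\beta|\,/\,(1 + C/E_{\rm kin})$,
$C = 0.1$ hartree, the literature default) is applied after hop
resolution — the ordering is a convention, stated here because the
alternatives are not uniquely fixed by the method literature.

Because velocity Verlet is symplectic, the total-energy error on a smooth
surface is a *bounded oscillation* of amplitude
$O((\omega\Delta t)^2 E_{\rm vib})$ — about 1e-4 hartree at
$\Delta t = 0.5$ fs and $\omega = 0.015$ — with essentially no secular
trend. We therefore quantify "drift" as the linear-trend slope of
$E_{\rm total}(t)$ times 1000 steps; on the bundled two-mode model this is
below 1e-8 hartree. Crossing a sharp avoided intersection in one step, and
the surface switch at a hop itself, add $O(\Delta t)$ bookkeeping offsets
of order 1e-4; these are inherent to discrete-step hopping, not to this
implementation, and shrink linearly with the step.

All propagator generators are anti-Hermitian ($-iH - T$ with $H$ Hermitian
and $T$ real antisymmetric equals $-i(H - iT)$ with $H - iT$ Hermitian),
so matrix exponentials are computed through the Hermitian
eigendecomposition — exactly unitary to roundoff, which is why norm drift
over 10,000+ electronic substeps stays at the 1e-13 level. The electronic
substep count (default 25, with linear midpoint interpolation of all
quantities) only matters for the coupling-based propagator; the
overlap-based local-diabatization propagator
$P = \hat O(S)^T \exp[-i(H_t + \hat O(S)H_{t+\Delta t}\hat O(S)^T)
\Delta t/2]$ is single-shot. Its midpoint-average form is our choice (the
method literature fixes only the construction idea); it reduces to
$e^{-iH\Delta t}$ for $S = I$, routes amplitudes through pure diabatic
passages exactly, and converges to the coupling-based propagator at
observed order ≈ 3 in $\Delta t$. It is the default, being robust at
trivial crossings where the coupling-based propagator fails (a failure the
tests assert, not merely avoid). The direct one-step integration of the
diagonal-basis equation of motion, including the
$U^\dagger\partial U/\partial t$ term by finite differences, is shipped as
`onestep_reference()` — a test oracle that agrees to 1e-5 on smooth
segments and is *documented to fail* at trivial crossings, which is the
motivation for the three-step construction.

## Initial conditions

`wigner_sample()` draws positions and momenta from the phase-space
distribution of the harmonic ground state — independent Gaussians of
variance 1/2 per dimensionless mode, i.e. position spread $1/(2\omega)$
and momentum spread $\omega/2$ in unscaled units, mean vibrational energy
$\omega/2$. At finite temperature the vibrational level is Boltzmann-drawn
per mode and the level's distribution is sampled by rejection from its
absolute value; excited-level distributions take negative values, so the
sign at the sampled point is logged as a per-sample weight — a stated
convention, since no standard resolution exists. `select_initial_states()`
assigns initial electronic states stochastically with delta-pulse weights
$p \propto f/\Delta E$ (switchable to $p \propto f$), normalized by the
ensemble maximum, in the spin-free basis by default (the delta-pulse
argument is only rigorous there; diagonal-basis selection is available
with a warning).

## Ensemble analysis

`populations()` implements six protocols: (a) mean diagonal quantum
populations, (b) classical state counts, (c) spin-free quantum populations
via $c^{\rm MCH} = U c^{\rm diag}$, (d) classical counts mapped
approximately onto spin-free states with $|U_{i\alpha}|^2$ weights (one
concrete realization of an approximation the method literature leaves
open), (e) quasi-diabatic populations by projecting onto a fixed reference
geometry's states through model-provided overlaps (again one stated
realization), and (f) histogram binning of trajectories whose scalar
property exceeds a threshold, e.g. an oscillator strength above 0.1.
Protocols a–c conserve the total population exactly.
`fit_kinetic_model()` fits first-order reaction networks through the
matrix-exponential solution with log-parameterised (hence nonnegative)
rates, and estimates errors by bootstrap over trajectories (200 replicates
by default; near-perfect bootstrap rate correlations trigger an
identifiability warning). Hop geometries and internal coordinates (bonds
in bohr, angles and dihedrals in degrees with the right-hand sign
convention) complete the analysis layer.

## What the synthetic models do and do not show

The bundled models reproduce the *structural* features that matter for
this algorithm family — spin–orbit-split avoided crossings, exactly
degenerate uncoupled multiplets, trivial crossings, laser-dressed states —
with constant coupling blocks and harmonic/linear diabats. They do not
emulate anharmonicity, geometry-dependent SOC, conical-intersection
topographies beyond linear coupling, or the electronic-structure noise of
on-the-fly calculations. Passing tests therefore certify the *method
machinery* (representations, propagation, tracking, hopping, sampling,
analysis) at desk scale, not the photophysics of any real molecule.

## Problem sizes and defaults

The shipped study conditions: the two-mode, five-state
singlet–singlet–triplet model `lvc_isc_demo()` (SOC scale 4e-4 hartree,
about 90 cm$^{-1}$); conservation runs of 500 nuclear × 25 electronic
steps at $\Delta t = 0.5$ fs; the six-state degenerate-crossing run of 45
steps; single-passage validation ensembles of 1000 trajectories per
coupling at $\Delta t = 10$ a.u. (the finer step resolves the crossing
region; at 20 a.u. a small positive discretization bias in the transition
fraction is visible at intermediate coupling); 10,000-sample
phase-space-moment checks; and 200-trajectory synthetic-decay fits with
100 bootstrap replicates. `scripts/acceptance.R` re-runs exactly these and
writes the resulting numbers as JSON.
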