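# hopdyn

Trajectory surface hopping with arbitrary electronic couplings, on
analytical model potentials, in R.

`hopdyn` is for method work on nonadiabatic dynamics with couplings beyond
the nonrelativistic Coulomb Hamiltonian — intersystem crossing through
spin–orbit coupling, and explicit laser–dipole interactions. Classical
nuclei are propagated on the eigenstates of the **total** electronic
Hamiltonian (the *diagonal* representation): the spin-free Hamiltonian
matrix over a few MCH states is augmented with a constant complex SOC block
and, optionally, a field–dipole term, and diagonalized every step,

$$H^{\mathrm{diag}} = U^\dagger H^{\mathrm{MCH}} U .$$

Amplitudes follow the three-step propagator
$c^{\mathrm{diag}}(t{+}\Delta t) = U^\dagger(t{+}\Delta t)\,
P^{\mathrm{MCH}}\,U(t)\,c^{\mathrm{diag}}(t)$ with $P^{\mathrm{MCH}}$ built
either from time-derivative couplings $v\cdot K$ or by overlap-based local
diabatization (robust through trivial crossings); eigenvector phases are
tracked across steps with the overlap-corrected algorithm
$U_{\mathrm{tracked}} = U_{\mathrm{raw}}\,[\hat O\hat C(U^\dagger_{\mathrm
prev} S U_{\mathrm{raw}})]^\dagger$; hops are drawn from the
propagator-based fewest-switches formula with kinetic-energy adjustment,
frustrated-hop handling and laser-hop classification; overcoherence is
damped by the energy-based decoherence correction. Initial conditions come
from harmonic-oscillator phase-space (Wigner) sampling plus stochastic
initial-state selection, and the analysis layer provides six population
protocols, first-order kinetic-model fitting with bootstrap errors,
hop-geometry extraction and internal coordinates — tibbles in, tibbles
out, with `autoplot()`, `tidy()` and `glance()` methods.

Everything electronic comes from analytical vibronic-coupling models
(`vibronic_model()`, `lvc_model()`) that emulate a quantum-chemistry
interface call per step: Hamiltonian with couplings, gradients, coupling
vectors, overlap with the previous geometry, dipoles. Two purpose-built
models — a linear avoided crossing with a closed-form transition
probability, and a degenerate-multiplet crossing that stresses phase
tracking — serve as validation oracles.

## Worked example

Intersystem crossing on the bundled two-mode singlet–singlet–triplet
model (about 90 cm⁻¹ spin–orbit coupling), 20 trajectories started in the
bright singlet from a ground-state phase-space sample:

```r
library(hopdyn)
model <- lvc_isc_demo()
ics <- wigner_sample(model$omega, n_samples = 20, seed = 101)
ics$state <- 2                       # bright singlet, spin-free basis
ens <- run_ensemble(model, ics, sim_settings(n_steps = 200, seed = 7))
ens
#> <sh_ensemble> 20 trajectories (20 ok)

pop <- populations(ens, protocol = "c")   # spin-free quantum populations
tail(tidyr::pivot_wider(pop, names_from = state,
                        values_from = population, names_prefix = "S"), 2)
#> # A tibble: 2 × 6
#>    time         S1    S2    S3    S4    S5
#>   <dbl>      <dbl> <dbl> <dbl> <dbl> <dbl>
#> 1 4113. 0.00000128 0.340 0.220 0.220 0.220
#> 2 4134. 0.00000129 0.334 0.222 0.222 0.222
```

After 100 fs, two thirds of the population has crossed to the three
triplet components (states 3–5), shared equally among them; the ground
state stays empty at this coupling strength and timescale. The ensemble
logged 170 accepted hops (`extract_hop_geometries(ens)`), and
`autoplot(pop)` draws the population curves. A kinetic model is fitted
with `fit_kinetic_model(pop, tibble::tibble(from = 2, to = 3),
n_bootstrap = 200)` and inspected with `tidy()`/`glance()`.

A shell entry point is included: `exec/hopdyn <sample|run|analyze>
--config <file>` covers the sampling → dynamics → analysis pipeline on
model files written with `write_model()`; all artifacts are human-readable
text with format tags and round-trip bit-identically.

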