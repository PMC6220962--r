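#' Vibronic model potentials
#'
#' A vibronic model is an analytical electronic-structure surrogate: for a
#' point in (dimensionless, mass-frequency-weighted) normal-mode space it
#' supplies everything a quantum-chemistry interface would per time step —
#' the total Hamiltonian in the basis of spin-free states (diagonal: spin-free
#' energies; off-diagonal: constant spin-orbit or other couplings), per-state
#' gradients, nonadiabatic-coupling vectors, the overlap matrix with the
#' previous geometry, and transition-dipole matrices.
#'
#' The diabatic potential matrix is
#' \deqn{V_{nn}(x) = \sum_i \tfrac{\omega_i}{2} x_i^2 + \epsilon_n +
#'       \sum_i \kappa_i^{(n)} x_i, \qquad
#'       V_{nm}(x) = \sum_i \lambda_i^{(nm)} x_i}
#' with the harmonic term optional per state (linear-diabat models such as the
#' two-state avoided-crossing validation model switch it off). States are
#' organised in spin-free groups (one group per multiplicity and magnetic
#' component); \eqn{\lambda} couplings exist only within a group, and the
#' constant coupling block `soc` (complex Hermitian) acts across all states.
#'
#' @param omega Per-mode frequencies (hartree; the dimensionless-coordinate
#'   convention, i.e. the classical mass of mode \eqn{i} is \eqn{1/\omega_i}).
#' @param epsilon Per-state vertical energy offsets (hartree).
#' @param kappa `n_states x n_modes` matrix of intrastate linear couplings
#'   (hartree); `NULL` for all-zero.
#' @param lambda `n_states x n_states x n_modes` array of interstate linear
#'   couplings (hartree), symmetric in the state pair and zero across groups;
#'   `NULL` for all-zero.
#' @param harmonic Logical per state: does the state carry the harmonic
#'   \eqn{\sum_i \omega_i x_i^2/2} term? Default all `TRUE`.
#' @param soc Constant complex Hermitian `n_states x n_states` coupling matrix
#'   (hartree); `NULL` for zero.
#' @param dipoles List of three constant complex Hermitian matrices (x, y, z
#'   components, a.u.); `NULL` for zero.
#' @param groups List of integer vectors partitioning `1:n_states` into
#'   spin-free groups (same multiplicity and magnetic component). Default: one
#'   group containing all states.
#' @param labels Optional tibble describing the states (columns such as
#'   `state`, `mult`, `ms`); carried along for bookkeeping.
#' @param masses Per-mode classical masses (a.u.). Default `1/omega`.
#' @param cartesian_map Optional list with elements `ref` (numeric vector,
#'   3*n_atoms reference Cartesian geometry in bohr) and `modes`
#'   (`3*n_atoms x n_modes` displacement matrix) defining a linear map from
#'   model coordinates to Cartesian geometries for the analysis module.
#' @return An object of class `vibronic_model`.
#' @seealso [lvc_model()], [lz_model()], [degenerate_crossing_model()],
#'   [evaluate_model()]
#' @export
vibronic_model <- function(omega, epsilon, kappa = NULL, lambda = NULL,
                           harmonic = NULL, soc = NULL, dipoles = NULL,
                           groups = NULL, labels = NULL, masses = NULL,
                           cartesian_map = NULL) {
  omega <- as.numeric(omega)
  epsilon <- as.numeric(epsilon)
  n_modes <- length(omega)
  n_states <- length(epsilon)
  if (is.null(harmonic)) harmonic <- rep(TRUE, n_states)
  harmonic <- rep_len(as.logical(harmonic), n_states)
  if (any(harmonic) && any(omega <= 0)) {
    stop("all mode frequencies must be positive", call. = FALSE)
  }
  if (is.null(kappa)) kappa <- matrix(0, n_states, n_modes)
  kappa <- matrix(as.numeric(kappa), n_states, n_modes)
  if (is.null(lambda)) lambda <- array(0, c(n_states, n_states, n_modes))
  lambda <- array(as.numeric(lambda), c(n_states, n_states, n_modes))
  if (is.null(groups)) groups <- list(seq_len(n_states))
  groups <- lapply(groups, as.integer)
  if (!setequal(unlist(groups), seq_len(n_states)) ||
      length(unlist(groups)) != n_states) {
    stop("'groups' must partition 1:n_states", call. = FALSE)
  }
  if (is.null(soc)) soc <- matrix(0i, n_states, n_states)
  soc <- as_complex_matrix(as.matrix(soc))
  assert_hermitian(soc, 1e-12, "soc")
  if (is.null(dipoles)) {
    dipoles <- replicate(3, matrix(0i, n_states, n_states), simplify = FALSE)
  }
  dipoles <- lapply(dipoles, function(m) {
    m <- as_complex_matrix(as.matrix(m))
    assert_hermitian(m, 1e-12, "dipole component")
    m
  })
  # lambda: symmetric in the pair, zero diagonal, zero across groups
  grp_of <- integer(n_states)
  for (g in seq_along(groups)) grp_of[groups[[g]]] <- g
  for (i in seq_len(n_modes)) {
    li <- lambda[, , i]
    if (max(abs(li - t(li))) > 1e-12) {
      stop("lambda must be symmetric in the state pair", call. = FALSE)
    }
    cross <- abs(li[outer(grp_of, grp_of, "!=")])
    if (length(cross) && max(cross) > 0) {
      stop("lambda couplings across spin-free groups must be zero", call. = FALSE)
    }
  }
  if (is.null(masses)) masses <- 1 / omega
  masses <- rep_len(as.numeric(masses), n_modes)
  structure(
    list(n_modes = n_modes, n_states = n_states, omega = omega,
         harmonic = harmonic, epsilon = epsilon, kappa = kappa,
         lambda = lambda, soc = soc, dipoles = dipoles, groups = groups,
         labels = labels, masses = masses, cartesian_map = cartesian_map),
    class = "vibronic_model"
  )
}

#' @export
print.vibronic_model <- function(x, ...) {
  cat("<vibronic_model> ", x$n_states, " states, ", x$n_modes, " mode(s), ",
      length(x$groups), " spin-free group(s)\n", sep = "")
  if (max(Mod(x$soc)) > 0) cat("  constant coupling block: yes\n")
  invisible(x)
}

#' Linear vibronic coupling model with explicit multiplet components
#'
#' Builds a [vibronic_model()] from spin-free-state input: each spin-free
#' state of multiplicity \eqn{m} is expanded into \eqn{m} explicit magnetic
#' components (e.g. a triplet into MS = -1, 0, +1) carrying identical
#' spin-free potentials. States are ordered by multiplicity, then magnetic
#' component, then spin-free index — so the spin-free groups are contiguous
#' blocks and the constant coupling matrix `soc` is supplied over all
#' components.
#'
#' @inheritParams vibronic_model
#' @param multiplicities Integer vector, one entry per spin-free state
#'   (1 = singlet, 3 = triplet, ...).
#' @param epsilon,kappa,lambda Per *spin-free* state quantities (see
#'   [vibronic_model()]); they are replicated over the magnetic components.
#' @param soc,dipoles Constant matrices over the full set of expanded
#'   components (dimension `sum(multiplicities)`).
#' @return A `vibronic_model` whose `labels` tibble records multiplicity,
#'   magnetic component and spin-free index of every expanded state.
#' @examples
#' m <- lvc_model(omega = c(0.01, 0.015), multiplicities = c(1, 1),
#'                epsilon = c(0, 0.1))
#' m$n_states
#' @export
lvc_model <- function(omega, multiplicities, epsilon, kappa = NULL,
                      lambda = NULL, soc = NULL, dipoles = NULL,
                      masses = NULL, cartesian_map = NULL) {
  n_sf <- length(epsilon)
  n_modes <- length(omega)
  multiplicities <- rep_len(as.integer(multiplicities), n_sf)
  if (is.null(kappa)) kappa <- matrix(0, n_sf, n_modes)
  kappa <- matrix(as.numeric(kappa), n_sf, n_modes)
  if (is.null(lambda)) lambda <- array(0, c(n_sf, n_sf, n_modes))
  lambda <- array(as.numeric(lambda), c(n_sf, n_sf, n_modes))
  # expansion order: multiplicity, then MS, then spin-free index
  lab <- list()
  for (m in sort(unique(multiplicities))) {
    sf <- which(multiplicities == m)
    for (ms in seq(-(m - 1) / 2, (m - 1) / 2, by = 1)) {
      for (s in sf) lab[[length(lab) + 1L]] <- c(m, ms, s)
    }
  }
  lab <- do.call(rbind, lab)
  labels <- tibble::tibble(state = seq_len(nrow(lab)), mult = lab[, 1],
                           ms = lab[, 2], sf_state = as.integer(lab[, 3]))
  n_tot <- nrow(labels)
  eps_x <- epsilon[labels$sf_state]
  kap_x <- kappa[labels$sf_state, , drop = FALSE]
  lam_x <- array(0, c(n_tot, n_tot, n_modes))
  groups <- list()
  key <- paste(labels$mult, labels$ms)
  for (k in unique(key)) {
    idx <- which(key == k)
    groups[[length(groups) + 1L]] <- idx
    lam_x[idx, idx, ] <- lambda[labels$sf_state[idx], labels$sf_state[idx], ,
                                drop = FALSE]
  }
  if (!is.null(soc) && nrow(as.matrix(soc)) != n_tot) {
    stop("soc must be given over all ", n_tot, " expanded components",
         call. = FALSE)
  }
  vibronic_model(omega = omega, epsilon = eps_x, kappa = kap_x,
                 lambda = lam_x, soc = soc, dipoles = dipoles,
                 groups = groups, labels = labels, masses = masses,
                 cartesian_map = cartesian_map)
}

#' Two-state linear avoided-crossing validation model
#'
#' One-dimensional two-state model with diabatic potentials \eqn{\pm a x} and
#' a constant coupling \eqn{b} (held in the constant coupling block, so the
#' diabats are the spin-free states and the adiabats are the
#' total-Hamiltonian eigenstates). The adiabatic gap at \eqn{x = 0} is
#' \eqn{2b}. Used to validate the hopping machinery against the closed-form
#' single-passage transition probability
#' \eqn{P = \exp(-2\pi b^2 / (2 a v))}.
#'
#' @param a Diabatic slope (hartree per coordinate unit), `a > 0`.
#' @param b Constant diabatic coupling (hartree), `b >= 0`.
#' @param mass Particle mass (a.u.).
#' @return A `vibronic_model`.
#' @export
lz_model <- function(a, b, mass = 2000) {
  stopifnot(a > 0, b >= 0, mass > 0)
  vibronic_model(
    omega = 1, epsilon = c(0, 0), kappa = matrix(c(a, -a), 2, 1),
    harmonic = c(FALSE, FALSE),
    soc = matrix(c(0, b, b, 0), 2, 2),
    groups = list(1L, 2L), masses = mass,
    labels = tibble::tibble(state = 1:2, mult = 1, ms = 0, sf_state = 1:2)
  )
}

#' Degenerate-crossing phase-tracking test model
#'
#' One-dimensional six-state model: two harmonic oscillator states coupled to
#' each other by a constant complex coupling, crossing a set of four exactly
#' degenerate flat states that are uncoupled to everything. The populated
#' oscillator shares a spin-free group with the flat multiplet, so when its
#' energy sweeps through the multiplet the energy-ordered spin-free states
#' relabel in a single time step — a simultaneous multi-state trivial
#' crossing. This is the canonical stress test for overlap-based phase
#' tracking: the overlap-corrected algorithm transfers populations completely
#' between the crossing partners while the projection-only variant misassigns
#' them.
#'
#' @param omega Oscillator frequency (hartree).
#' @param eps_flat Energy of the four degenerate flat states (hartree).
#' @param eps_upper Energy offset of the second oscillator (hartree); keep it
#'   above the energies visited so only the first oscillator crosses the
#'   multiplet during dynamics.
#' @param coupling Constant complex coupling between the two oscillator states
#'   (hartree).
#' @param scan_range Scan interval used to verify that the coupled adiabats
#'   cross the multiplet at least twice; a configuration error is raised
#'   otherwise.
#' @return A `vibronic_model` with state 1 = populated oscillator,
#'   states 2-5 = flat multiplet, state 6 = second oscillator.
#' @export
degenerate_crossing_model <- function(omega = 0.005, eps_flat = 0.05,
                                      eps_upper = 0.25,
                                      coupling = 5e-4 + 5e-4i,
                                      scan_range = c(-10, 10)) {
  soc <- matrix(0i, 6, 6)
  soc[1, 6] <- coupling
  soc[6, 1] <- Conj(coupling)
  model <- vibronic_model(
    omega = omega,
    epsilon = c(0, rep(eps_flat, 4), eps_upper),
    harmonic = c(TRUE, rep(FALSE, 4), TRUE),
    soc = soc,
    groups = list(1:5, 6L)
  )
  # require >= 2 sign changes of (coupled adiabat - multiplet) along the scan
  xs <- seq(scan_range[1], scan_range[2], length.out = 601)
  gap <- vapply_num(xs, function(x) {
    v1 <- omega * x^2 / 2
    v2 <- omega * x^2 / 2 + eps_upper
    h2 <- matrix(c(v1, Conj(coupling), coupling, v2), 2, 2)
    min(eigen(h2, symmetric = TRUE, only.values = TRUE)$values) - eps_flat
  })
  n_cross <- sum(diff(sign(gap)) != 0)
  if (n_cross < 2) {
    stop("model parameters give fewer than two crossings in the scan range",
         call. = FALSE)
  }
  attr(model, "n_crossings_scan") <- n_cross
  model
}

# diabatic potential matrix V(x) (real symmetric)
diabatic_matrix <- function(model, x) {
  n <- model$n_states
  harm <- sum(model$omega * x^2) / 2
  v <- matrix(0, n, n)
  for (i in seq_len(model$n_modes)) {
    v <- v + matrix(model$lambda[, , i], n, n) * x[i]
  }
  diag(v) <- ifelse(model$harmonic, harm, 0) + model$epsilon +
    as.numeric(model$kappa %*% x)
  v
}

# dV/dx_i, one real symmetric matrix per mode
diabatic_gradient <- function(model, x) {
  n <- model$n_states
  out <- array(0, c(n, n, model$n_modes))
  for (i in seq_len(model$n_modes)) {
    di <- matrix(model$lambda[, , i], n, n)
    diag(di) <- ifelse(model$harmonic, model$omega[i] * x[i], 0) +
      model$kappa[, i]
    out[, , i] <- di
  }
  out
}

# eigendecomposition of one spin-free block, ascending, deterministic signs;
# exactly diagonal blocks are sorted with a stable permutation so that exact
# degeneracies (flat multiplets) keep the model's state order
block_eigen <- function(vg) {
  n <- nrow(vg)
  off <- vg
  diag(off) <- 0
  if (max(abs(off)) == 0) {
    ord <- order(diag(vg))
    w <- diag(n)[, ord, drop = FALSE]
    return(list(values = diag(vg)[ord], vectors = w))
  }
  e <- eigen(vg, symmetric = TRUE)
  idx <- order(e$values)
  w <- e$vectors[, idx, drop = FALSE]
  for (j in seq_len(n)) {
    i <- which.max(abs(w[, j]))
    if (w[i, j] < 0) w[, j] <- -w[, j]
  }
  list(values = e$values[idx], vectors = w)
}

#' Evaluate a vibronic model at a geometry
#'
#' Diagonalises the spin-free diabatic matrix blockwise (per spin-free group,
#' eigenvalues ascending within each block), then assembles the per-step
#' electronic quantities in the basis of spin-free states: the total
#' Hamiltonian `diag(E) + W' soc W`, Hellmann-Feynman gradients
#' \eqn{g_\mu = w_\mu^T (\partial V/\partial x) w_\mu}, analytic
#' nonadiabatic couplings
#' \eqn{K_{\mu\nu} = w_\mu^T (\partial V/\partial x) w_\nu / (E_\nu - E_\mu)},
#' the overlap matrix with a previous evaluation, and transformed dipoles.
#'
#' @param model A [vibronic_model()].
#' @param x Coordinate vector (length `n_modes`).
#' @param prev A previous `mch_data` evaluation (for the overlap matrix) or
#'   `NULL`, in which case the overlap is the identity.
#' @param nac_threshold Spin-free gaps below this (hartree) have their
#'   coupling element set to zero and flagged in `nac_zeroed` instead of
#'   diverging.
#' @return An object of class `mch_data`: list with `hamiltonian` (complex
#'   Hermitian), `energies_sf`, `gradients` (`n_states x n_modes`), `nacs`
#'   (`n_states x n_states x n_modes`, antisymmetric), `overlap`, `dipoles`,
#'   `W` (spin-free eigenvectors), `nac_zeroed`, `x`.
#' @export
evaluate_model <- function(model, x, prev = NULL, nac_threshold = 1e-8) {
  UseMethod("evaluate_model")
}

#' @export
evaluate_model.vibronic_model <- function(model, x, prev = NULL,
                                          nac_threshold = 1e-8) {
  x <- as.numeric(x)
  if (length(x) != model$n_modes) {
    stop("coordinate vector has length ", length(x), ", expected ",
         model$n_modes, call. = FALSE)
  }
  n <- model$n_states
  v <- diabatic_matrix(model, x)
  dv <- diabatic_gradient(model, x)
  w <- matrix(0, n, n)
  e_sf <- numeric(n)
  for (g in model$groups) {
    be <- block_eigen(v[g, g, drop = FALSE])
    w[g, g] <- be$vectors
    e_sf[g] <- be$values
  }
  ham <- diag(complex(real = e_sf), n) + Conj(t(w)) %*% model$soc %*% w
  grads <- matrix(0, n, model$n_modes)
  nacs <- array(0, c(n, n, model$n_modes))
  de <- outer(e_sf, e_sf, function(a, b) b - a)  # de[mu, nu] = E_nu - E_mu
  zeroed <- matrix(FALSE, n, n)
  small <- abs(de) < nac_threshold
  for (i in seq_len(model$n_modes)) {
    gmat <- t(w) %*% dv[, , i] %*% w
    grads[, i] <- diag(gmat)
    k <- gmat / de
    k[small] <- 0
    diag(k) <- 0
    zeroed <- zeroed | (small & !diag(n) & abs(gmat) > 1e-14)
    nacs[, , i] <- k
  }
  overlap <- if (is.null(prev)) diag(n) else t(prev$W) %*% w
  dip <- lapply(model$dipoles, function(m) Conj(t(w)) %*% m %*% w)
  structure(
    list(hamiltonian = ham, energies_sf = e_sf, gradients = grads,
         nacs = nacs, overlap = overlap, dipoles = dip, W = w,
         nac_zeroed = zeroed, x = x),
    class = "mch_data"
  )
}

#' Laser pulse definition
#'
#' A classical electric field \eqn{E(t) = E_0\, f(t) \cos(\omega_L (t - t_0)
#' + \phi)\, \hat e} with a constant or Gaussian envelope \eqn{f(t)}.
#'
#' @param e0 Field amplitude (a.u.).
#' @param omega Central frequency (hartree).
#' @param polarization Polarization vector; normalised to unit length.
#' @param envelope `"constant"` or `"gaussian"`.
#' @param t0 Envelope centre (a.u. time, Gaussian envelope).
#' @param fwhm Intensity-envelope full width at half maximum (a.u. time,
#'   Gaussian envelope).
#' @param phase Carrier phase (radians).
#' @return An object of class `laser_pulse`. Its `spectral_fwhm` element is
#'   the Fourier-limited spectral width (hartree; 0 for a constant envelope),
#'   used for the laser-hop energy-matching tolerance.
#' @export
laser_pulse <- function(e0, omega, polarization = c(0, 0, 1),
                        envelope = c("constant", "gaussian"),
                        t0 = 0, fwhm = NULL, phase = 0) {
  envelope <- match.arg(envelope)
  pol <- as.numeric(polarization)
  nrm <- sqrt(sum(pol^2))
  if (nrm == 0) stop("polarization must be nonzero", call. = FALSE)
  pol <- pol / nrm
  if (envelope == "gaussian" && (is.null(fwhm) || fwhm <= 0)) {
    stop("a gaussian envelope needs a positive fwhm", call. = FALSE)
  }
  spectral <- if (envelope == "gaussian") 4 * log(2) / fwhm else 0
  structure(list(e0 = e0, omega = omega, polarization = pol,
                 envelope = envelope, t0 = t0, fwhm = fwhm, phase = phase,
                 spectral_fwhm = spectral),
            class = "laser_pulse")
}

envelope_at <- function(pulse, t) {
  switch(pulse$envelope,
         constant = 1,
         gaussian = exp(-4 * log(2) * (t - pulse$t0)^2 / pulse$fwhm^2))
}

#' Electric field of a pulse at a time
#'
#' @param pulse A [laser_pulse()].
#' @param t Time (a.u.).
#' @return Numeric length-3 field vector (a.u.).
#' @export
field_at <- function(pulse, t) {
  pulse$e0 * envelope_at(pulse, t) *
    cos(pulse$omega * (t - pulse$t0) + pulse$phase) * pulse$polarization
}

#' Add the field-dipole interaction to an electronic evaluation
#'
#' Replaces the Hamiltonian by \eqn{H - \sum_k \mu_k E_k(t)}; all other
#' fields of the evaluation are unchanged. Hermiticity is preserved because
#' the dipole matrices are Hermitian and the field is real.
#'
#' @param mch An `mch_data` object (from [evaluate_model()]).
#' @param pulse A [laser_pulse()] or `NULL` (returned unchanged).
#' @param t Time (a.u.).
#' @return The modified `mch_data`.
#' @export
couple_laser <- function(mch, pulse, t) {
  if (is.null(pulse)) return(mch)
  ef <- field_at(pulse, t)
  h <- mch$hamiltonian
  for (k in 1:3) {
    if (ef[k] != 0) h <- h - mch$dipoles[[k]] * ef[k]
  }
  mch$hamiltonian <- h
  mch
}
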