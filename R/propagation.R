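#' Electronic propagator from Hamiltonian and time-derivative couplings
#'
#' Builds the one-nuclear-step propagator in the spin-free basis as an
#' ordered product of short-time exponentials,
#' \deqn{P = \prod_k \exp[(-i H_k - T_k)\,\delta t]}
#' with all quantities linearly interpolated between the two nuclear steps
#' and evaluated at the substep midpoints. \eqn{T = v\cdot K} is the real
#' antisymmetric time-derivative coupling matrix, so each generator is
#' anti-Hermitian and each factor exactly unitary.
#'
#' @param h_t,h_tdt Total Hamiltonian at the two ends of the step (complex
#'   Hermitian, hartree).
#' @param t_t,t_tdt Time-derivative coupling matrices at the two ends (real
#'   antisymmetric, a.u.).
#' @param dt Nuclear time step (a.u.).
#' @param n_substeps Number of electronic substeps (default 25).
#' @return Complex unitary propagator matrix.
#' @export
propagator_nac <- function(h_t, h_tdt, t_t, t_tdt, dt, n_substeps = 25L) {
  n_substeps <- max(1L, as.integer(n_substeps))
  n <- nrow(h_t)
  p <- diag(nrow = n) + 0i
  delta <- dt / n_substeps
  dh <- h_tdt - h_t
  dtm <- t_tdt - t_t
  for (k in seq_len(n_substeps)) {
    f <- (k - 0.5) / n_substeps
    h <- h_t + f * dh
    tm <- t_t + f * dtm
    # exp[(-iH - T) dt] = exp[-i (H - iT) dt]; H - iT is Hermitian
    p <- unitary_exp(h - 1i * tm, delta) %*% p
  }
  p
}

#' Electronic propagator by local diabatization
#'
#' Uses the overlap matrix between the spin-free states of consecutive steps
#' (\eqn{S_{\alpha\beta} = \langle\Psi_\alpha(t)|\Psi_\beta(t+\Delta t)
#' \rangle}) to construct a step-local diabatic frame — the frame of the
#' old-step states — in which the Hamiltonian is propagated with a single
#' midpoint exponential and transformed back:
#' \deqn{P = T^T \exp[-i\,(H_t + T H_{t+\Delta t} T^T)\,\Delta t/2]},
#' \eqn{T = \hat O(S)} (the orthonormalized overlap; \eqn{T H_{t+\Delta t}
#' T^T} is the new Hamiltonian expressed over the old states, and \eqn{T^T}
#' maps the propagated amplitudes onto the new states). No coupling vectors
#' are needed, and the propagator stays smooth through trivial crossings
#' where \eqn{S} is (close to) a permutation — the amplitude of an old state
#' is routed onto the new state of the same character. Reduces to
#' \eqn{\exp(-iH\Delta t)} for \eqn{S = I} and constant \eqn{H}.
#'
#' @param h_t,h_tdt Total Hamiltonian at the two ends of the step.
#' @param s Sign-fixed real overlap matrix between the steps.
#' @param dt Nuclear time step (a.u.).
#' @return Complex unitary propagator matrix.
#' @export
propagator_ld <- function(h_t, h_tdt, s, dt) {
  tm <- loewdin_orthonormalize(s)
  m <- h_t + tm %*% h_tdt %*% Conj(t(tm))
  t(tm) %*% unitary_exp(m, dt / 2)
}

#' Advance the diagonal-basis amplitudes over one nuclear step
#'
#' The three-step propagation: transform the amplitudes to the spin-free
#' basis with \eqn{U(t)}, propagate there, transform back with
#' \eqn{U^\dagger(t+\Delta t)}:
#' \deqn{c^{diag}(t+\Delta t) = U^\dagger(t+\Delta t)\, P\, U(t)\,
#'   c^{diag}(t)}
#' The arbitrary phases of the raw eigenvectors cancel inside the product, so
#' the diagonal amplitudes are well defined even across trivial crossings
#' where a one-step integration of the diagonal-basis equation of motion
#' fails.
#'
#' @param c_diag Complex amplitude vector at time `t`.
#' @param u_t,u_tdt (Tracked) transformation matrices at the two steps.
#' @param p_mch Spin-free propagator (from [propagator_ld()] or
#'   [propagator_nac()]).
#' @return List with `c` (new amplitudes) and `p_diag` (the diagonal-basis
#'   propagator, needed by the hopping-probability formula).
#' @export
step_coefficients <- function(c_diag, u_t, u_tdt, p_mch) {
  p_diag <- Conj(t(u_tdt)) %*% p_mch %*% u_t
  list(c = as.vector(p_diag %*% c_diag), p_diag = p_diag)
}

#' One-step direct integration of the diagonal-basis equation of motion
#'
#' Reference integrator (test oracle): integrates
#' \deqn{\dot c = -[\,i U^\dagger H U + U^\dagger T U +
#'   U^\dagger \partial U/\partial t\,]\,c}
#' with a fourth-order Runge-Kutta scheme on a fine grid, the
#' \eqn{U^\dagger\partial U/\partial t} term evaluated by finite differences
#' of the supplied transformation-matrix series. Valid on smooth segments; it
#' is *documented to fail* near trivial crossings where \eqn{U} changes
#' abruptly — the motivation for the three-step propagator.
#'
#' @param c_diag Amplitudes at the start of the step.
#' @param h_t,h_tdt Total Hamiltonian at the two ends (linearly interpolated
#'   in between).
#' @param t_t,t_tdt Time-derivative coupling matrices at the two ends.
#' @param u_series List of transformation matrices on an equidistant grid
#'   spanning the step (at least two entries; more give a more accurate
#'   \eqn{\partial U/\partial t}).
#' @param dt Nuclear time step (a.u.).
#' @return Complex amplitude vector at `t + dt`.
#' @export
onestep_reference <- function(c_diag, h_t, h_tdt, t_t, t_tdt, u_series, dt) {
  ng <- length(u_series)
  stopifnot(ng >= 2)
  n <- length(c_diag)
  tau <- dt / (ng - 1)
  # grid-node generator matrices A(t) = i U'HU + U'TU + U' dU/dt
  gen <- vector("list", ng)
  for (k in seq_len(ng)) {
    f <- (k - 1) / (ng - 1)
    h <- h_t + f * (h_tdt - h_t)
    tm <- t_t + f * (t_tdt - t_t)
    u <- u_series[[k]]
    dudt <- if (k == 1) {
      (u_series[[2]] - u_series[[1]]) / tau
    } else if (k == ng) {
      (u_series[[ng]] - u_series[[ng - 1]]) / tau
    } else {
      (u_series[[k + 1]] - u_series[[k - 1]]) / (2 * tau)
    }
    gen[[k]] <- 1i * Conj(t(u)) %*% h %*% u + Conj(t(u)) %*% tm %*% u +
      Conj(t(u)) %*% dudt
  }
  interp <- function(tt) {
    # linear interpolation of the generator between grid nodes
    pos <- tt / tau
    k <- min(max(floor(pos), 0), ng - 2)
    f <- pos - k
    (1 - f) * gen[[k + 1]] + f * gen[[k + 2]]
  }
  c_cur <- c_diag
  for (k in seq_len(ng - 1)) {
    t0 <- (k - 1) * tau
    a1 <- interp(t0)
    a2 <- interp(t0 + tau / 2)
    a4 <- interp(t0 + tau)
    k1 <- -a1 %*% c_cur
    k2 <- -a2 %*% (c_cur + tau / 2 * k1)
    k3 <- -a2 %*% (c_cur + tau / 2 * k2)
    k4 <- -a4 %*% (c_cur + tau * k3)
    c_cur <- c_cur + tau / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  as.vector(c_cur)
}
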