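#' Fewest-switches hopping probabilities in the diagonal basis
#'
#' The default hopping formula, built from the diagonal-basis propagator
#' rather than the time-derivative coupling (whose
#' \eqn{U^\dagger\partial U/\partial t} part is numerically treacherous):
#' \deqn{h_{\beta\to\alpha} =
#'   \Big(1 - \frac{|c_\beta(t+\Delta t)|^2}{|c_\beta(t)|^2}\Big)
#'   \frac{\Re[\,c_\alpha(t+\Delta t)\,P^*_{\alpha\beta}\,c^*_\beta(t)\,]}
#'        {|c_\beta(t)|^2 -
#'         \Re[\,c_\beta(t+\Delta t)\,P^*_{\beta\beta}\,c^*_\beta(t)\,]}}
#' Hops occur only when the active population decreases (the prefactor is
#' otherwise negative and everything clamps to zero). When
#' \eqn{c(t+\Delta t) = P c(t)} exactly, unitarity gives
#' \eqn{\sum_{\alpha\neq\beta} h = 1 - |c_\beta(t+\Delta t)|^2 /
#' |c_\beta(t)|^2} before clamping.
#'
#' @param c_t,c_tdt Diagonal amplitudes before and after the step.
#' @param p_diag Diagonal-basis propagator (from [step_coefficients()]).
#' @param active Index of the active state \eqn{\beta}.
#' @param clamp Clamp negative entries to zero (the probability
#'   interpretation); disable to inspect the raw algebraic values.
#' @return Vector of hopping probabilities (entry `active` is zero).
#' @export
hop_probabilities_fs <- function(c_t, c_tdt, p_diag, active,
                                    clamp = TRUE) {
  n <- length(c_t)
  zero <- numeric(n)
  pb2 <- Mod(c_t[active])^2
  if (pb2 <= 0) {
    warning("active state has zero population; no hopping probabilities",
            call. = FALSE)
    return(zero)
  }
  pref <- 1 - Mod(c_tdt[active])^2 / pb2
  if (clamp && pref <= 0) return(zero)   # fewest switches: no loss, no hops
  den <- pb2 - Re(c_tdt[active] * Conj(p_diag[active, active]) *
                    Conj(c_t[active]))
  if (abs(den) < 1e-300) {
    warning("vanishing denominator in the hopping formula; probabilities zeroed",
            call. = FALSE)
    return(zero)
  }
  num <- Re(c_tdt * Conj(p_diag[, active]) * Conj(c_t[active]))
  h <- pref * num / den
  h[active] <- 0
  if (clamp) h <- pmax(h, 0)
  h
}

#' Global-flux hopping probabilities
#'
#' Alternative hopping formula using only population changes: with
#' \eqn{b_\alpha = |c_\alpha(t+\Delta t)|^2 - |c_\alpha(t)|^2}, the active
#' state hops only if it loses population (\eqn{b_\beta < 0}), distributing
#' \eqn{-b_\beta/|c_\beta(t)|^2} over the gaining states in proportion to
#' their gains. Useful when population flows through a classically forbidden
#' intermediate.
#'
#' @inheritParams hop_probabilities_fs
#' @return Vector of hopping probabilities.
#' @export
hop_probabilities_gfsh <- function(c_t, c_tdt, active) {
  n <- length(c_t)
  zero <- numeric(n)
  pb2 <- Mod(c_t[active])^2
  if (pb2 <= 0) {
    warning("active state has zero population; no hopping probabilities",
            call. = FALSE)
    return(zero)
  }
  b <- Mod(c_tdt)^2 - Mod(c_t)^2
  if (b[active] >= 0) return(zero)
  gain <- b > 0
  if (!any(gain)) {
    warning("active state loses population but no state gains; probabilities zeroed",
            call. = FALSE)
    return(zero)
  }
  h <- zero
  h[gain] <- b[gain] / sum(b[gain]) * (-b[active]) / pb2
  h
}

#' Stochastic hop attempt with kinetic-energy adjustment
#'
#' Compares one uniform draw against the cumulative hopping probabilities
#' (ordered by state index) to pick a candidate state, then settles the
#' energetics: on a hop the potential-energy change \eqn{\Delta E} is taken
#' from (or given to) the kinetic energy along the chosen direction — the
#' full velocity vector or the component parallel to a coupling vector — so
#' that \eqn{E_{kin} + E_{active}} is conserved. If the available kinetic
#' energy along that direction is insufficient the hop is *frustrated*: the
#' active state is kept and, optionally, the parallel velocity component is
#' inverted. While a laser field is active, a hop whose \eqn{|\Delta E|}
#' matches the photon energy within tolerance is accepted without any
#' rescaling (the energy came from the field).
#'
#' @param probs Hopping-probability vector (from one of the probability
#'   functions).
#' @param draw Uniform random number in `[0, 1)`.
#' @param active Current active state index.
#' @param energies Diagonal potential energies (hartree).
#' @param v Velocity vector (a.u.).
#' @param masses Per-coordinate masses (a.u.).
#' @param mode `"nac-parallel"`, `"full-velocity"` or `"none"` (accept
#'   without adjustment; total energy is then not conserved).
#' @param reflect Invert the parallel velocity component on a frustrated
#'   hop?
#' @param nac_direction Coupling vector between the states (for
#'   `"nac-parallel"`); falls back to the full velocity vector when absent
#'   or numerically zero.
#' @param laser_active Is a field present at this step?
#' @param laser_omega Photon energy (hartree).
#' @param laser_tol Energy-matching tolerance (hartree).
#' @return A `hop_decision` list: `old`, `candidate`, `probs`, `draw`,
#'   `outcome` (`"no-hop"`, `"hop"`, `"frustrated"`, `"laser-hop"`),
#'   `v_before`, `v_after`, `delta_e`.
#' @export
attempt_hop <- function(probs, draw, active, energies, v, masses,
                        mode = c("nac-parallel", "full-velocity", "none"),
                        reflect = FALSE, nac_direction = NULL,
                        laser_active = FALSE, laser_omega = NULL,
                        laser_tol = NULL) {
  mode <- match.arg(mode)
  res <- list(old = active, candidate = NA_integer_, probs = probs,
              draw = draw, outcome = "no-hop", v_before = v, v_after = v,
              delta_e = 0)
  cum <- cumsum(probs)
  cand <- which(draw < cum)[1]
  if (is.na(cand)) return(res)
  res$candidate <- cand
  de <- energies[cand] - energies[active]
  res$delta_e <- de
  if (laser_active && !is.null(laser_omega) &&
      abs(abs(de) - laser_omega) < (laser_tol %||% 0)) {
    res$outcome <- "laser-hop"
    return(res)
  }
  if (mode == "none" || de == 0) {
    res$outcome <- "hop"
    return(res)
  }
  dir <- NULL
  if (mode == "nac-parallel" && !is.null(nac_direction) &&
      sqrt(sum(nac_direction^2)) > 1e-12) {
    dir <- nac_direction
  }
  if (is.null(dir)) dir <- v   # full-velocity rescaling
  a <- sum(masses * dir^2) / 2
  bq <- sum(masses * v * dir)
  if (a <= 0) {
    res$outcome <- "frustrated"
    return(res)
  }
  disc <- bq^2 - 4 * a * de
  if (disc < 0) {
    res$outcome <- "frustrated"
    if (reflect) res$v_after <- v - 2 * (bq / (2 * a)) * dir
    return(res)
  }
  # the root with the smaller velocity change
  g1 <- (bq - sqrt(disc)) / (2 * a)
  g2 <- (bq + sqrt(disc)) / (2 * a)
  gam <- if (abs(g1) <= abs(g2)) g1 else g2
  res$v_after <- v - gam * dir
  res$outcome <- "hop"
  res
}

#' Energy-based decoherence correction
#'
#' Damps the amplitudes of the inactive states with the phenomenological
#' rate \eqn{1/\tau_\alpha}, \eqn{\tau_\alpha = \frac{1}{|E_\alpha -
#' E_\beta|}\big(1 + \frac{C}{E_{kin}}\big)} (a.u.), then rescales the
#' active amplitude (phase kept) so the total norm returns to one. States
#' exactly degenerate with the active state are left undamped.
#'
#' @param c_diag Complex amplitude vector.
#' @param active Active state index.
#' @param energies Diagonal potential energies (hartree).
#' @param e_kin Current kinetic energy (hartree); non-positive values skip
#'   the correction.
#' @param c_param Decoherence constant C (hartree), default 0.1.
#' @param dt Time step (a.u.).
#' @return The corrected amplitude vector (unit norm).
#' @export
apply_decoherence_edc <- function(c_diag, active, energies, e_kin,
                                  c_param = 0.1, dt) {
  if (e_kin <= 0) return(c_diag)
  n <- length(c_diag)
  fac <- 1 + c_param / e_kin
  for (a in seq_len(n)) {
    if (a == active) next
    de <- abs(energies[a] - energies[active])
    if (de == 0) next
    c_diag[a] <- c_diag[a] * exp(-dt * de / fac)
  }
  pop_other <- sum(Mod(c_diag[-active])^2)
  target <- sqrt(max(0, 1 - pop_other))
  mb <- Mod(c_diag[active])
  c_diag[active] <- if (mb > 0) c_diag[active] * (target / mb) else
    complex(real = target)
  c_diag
}
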