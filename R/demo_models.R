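#' Two-mode intersystem-crossing demonstration model
#'
#' A small linear-vibronic-coupling model used throughout the tests and the
#' worked examples: two modes (frequencies 0.010 and 0.015 hartree), two
#' singlet states and one triplet (five explicit states), with intrastate
#' shifts on the excited states, an interstate singlet-singlet coupling, and
#' a constant complex singlet-triplet coupling of a few hundred
#' reciprocal centimetres — the regime where ultrafast intersystem crossing
#' competes with internal conversion.
#'
#' @param soc_strength Magnitude scale of the singlet-triplet coupling
#'   (hartree). The default, 4e-4 (about 90 reciprocal centimetres), is
#'   typical of organic chromophores with close-lying singlet and triplet
#'   states.
#' @return A [vibronic_model()] with 5 states (S0, S1, T1 with
#'   MS = -1, 0, +1) and 2 modes.
#' @export
lvc_isc_demo <- function(soc_strength = 4e-4) {
  omega <- c(0.010, 0.015)
  # spin-free states: S0, S1, T1
  epsilon <- c(0, 0.12, 0.10)
  kappa <- rbind(c(0, 0),
                 c(0.008, -0.006),
                 c(-0.005, 0.007))
  lambda <- array(0, c(3, 3, 2))
  lambda[1, 2, ] <- lambda[2, 1, ] <- c(0.004, 0.003)
  # expanded order: S0(1), S1(2), T1 ms=-1(3), ms=0(4), ms=+1(5)
  s <- soc_strength
  soc <- matrix(0i, 5, 5)
  soc[2, 3] <- s * (0.6 + 0.8i)
  soc[2, 4] <- s * (1.0 + 0.0i)
  soc[2, 5] <- s * (0.6 - 0.8i)
  soc[1, 3] <- s * (0.2 - 0.3i)
  soc[1, 5] <- s * (0.2 + 0.3i)
  soc <- soc + Conj(t(soc))
  # transition dipoles: bright S0-S1
  dx <- matrix(0i, 5, 5); dx[1, 2] <- dx[2, 1] <- 1.2
  dz <- matrix(0i, 5, 5); dz[1, 2] <- dz[2, 1] <- 0.4
  lvc_model(omega = omega, multiplicities = c(1, 1, 3), epsilon = epsilon,
            kappa = kappa, lambda = lambda, soc = soc,
            dipoles = list(dx, matrix(0i, 5, 5), dz))
}
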