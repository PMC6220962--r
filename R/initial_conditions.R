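# Laguerre polynomial L_n(x) by the three-term recurrence
laguerre <- function(n, x) {
  if (n == 0L) return(rep(1, length(x)))
  lm1 <- rep(1, length(x))
  l <- 1 - x
  if (n == 1L) return(l)
  for (k in 1L:(n - 1L)) {
    lnew <- ((2 * k + 1 - x) * l - k * lm1) / (k + 1)
    lm1 <- l
    l <- lnew
  }
  l
}

# phase-space quasi-distribution of harmonic level n at radius^2 = r2
# (dimensionless q, p), up to normalisation: (-1)^n L_n(2 r2) exp(-r2)
wigner_level <- function(n, r2) {
  (-1)^n * laguerre(n, 2 * r2) * exp(-r2)
}

# sample (q, p) from |W_n| by rejection; returns q, p and the sign of W_n
sample_wigner_level <- function(n) {
  if (n == 0L) {
    return(list(q = rnorm(1, sd = sqrt(0.5)), p = rnorm(1, sd = sqrt(0.5)),
                sign = 1))
  }
  rmax <- sqrt(2 * n + 1) + 4
  grid <- seq(0, rmax, length.out = 400)
  m <- max(abs(wigner_level(n, grid^2))) * 1.05
  repeat {
    q <- runif(1, -rmax, rmax)
    p <- runif(1, -rmax, rmax)
    wv <- wigner_level(n, q^2 + p^2)
    if (runif(1) * m < abs(wv)) {
      return(list(q = q, p = p, sign = sign(wv)))
    }
  }
}

#' Sample initial conditions from a harmonic-oscillator phase-space
#' distribution
#'
#' Draws positions and momenta from the phase-space (Wigner) distribution of
#' the vibrational ground state of each mode — independent Gaussians with
#' variance 1/2 in the dimensionless coordinate and its conjugate momentum,
#' i.e. position spread \eqn{1/(2\omega)} and momentum spread \eqn{\omega/2}
#' in unscaled (mass-weighted) units. At finite temperature each mode's
#' vibrational level is drawn from the Boltzmann distribution and the
#' corresponding level's distribution is sampled by rejection from its
#' absolute value; the distribution's sign at the sampled point is recorded
#' as a weight (excited-level phase-space distributions take negative
#' values — a documented convention, flagged per sample).
#'
#' Velocities are returned in the dimensionless-coordinate convention used
#' by the model layer (classical mode mass \eqn{1/\omega}), i.e.
#' \eqn{v = \omega p}.
#'
#' @param omega Per-mode frequencies (hartree).
#' @param n_samples Number of samples.
#' @param seed RNG seed (optional).
#' @param temperature Temperature in kelvin (0 = ground state only).
#' @return A tibble with columns `sample`, list-columns `x0` and `v0`,
#'   `sign_weight` (product of per-mode distribution signs) and a list-column
#'   `levels` (sampled vibrational level per mode).
#' @export
wigner_sample <- function(omega, n_samples, seed = NULL, temperature = 0) {
  if (any(omega <= 0)) stop("all frequencies must be positive", call. = FALSE)
  if (temperature < 0) stop("temperature must be >= 0", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  nm <- length(omega)
  kt <- temperature * au_units$k_boltzmann
  draw_level <- function(w) {
    if (kt <= 0) return(0L)
    # geometric distribution over harmonic levels, P(n) = q^n (1 - q)
    as.integer(floor(log(runif(1)) / (-w / kt)))
  }
  out <- vector("list", n_samples)
  for (s in seq_len(n_samples)) {
    q <- numeric(nm); p <- numeric(nm); lev <- integer(nm); sgn <- 1
    for (i in seq_len(nm)) {
      lev[i] <- draw_level(omega[i])
      sm <- sample_wigner_level(lev[i])
      q[i] <- sm$q; p[i] <- sm$p; sgn <- sgn * sm$sign
    }
    out[[s]] <- tibble::tibble(sample = s, x0 = list(q),
                               v0 = list(omega * p),
                               sign_weight = sgn, levels = list(lev))
  }
  dplyr::bind_rows(out)
}

#' Stochastic initial-state selection from an excitation spectrum
#'
#' Given per-sample vertical excitation energies and oscillator strengths,
#' selects the initial electronic state stochastically: each in-window state
#' gets weight \eqn{p \propto f/\Delta E} (the squared transition dipole of
#' a delta-pulse excitation; switchable to \eqn{p \propto f}); a sample is
#' accepted with probability equal to its total weight over the ensemble
#' maximum, and an accepted sample's state is drawn in proportion to the
#' state weights. Selection is performed in the spin-free basis by default
#' (the delta-pulse argument is only rigorous there); requesting the
#' diagonal basis logs a warning.
#'
#' @param spectrum Tibble with columns `sample`, `state`, `energy`
#'   (excitation energy, hartree, > 0) and `fosc` (oscillator strength).
#' @param window Length-2 numeric energy window (hartree).
#' @param seed RNG seed (optional).
#' @param weight `"f_over_e"` (delta pulse) or `"f"`.
#' @param basis `"mch"` or `"diagonal"` (warned).
#' @return A tibble with one row per sample: `sample`, `accepted`, `state`
#'   (`NA` if rejected), `total_weight`, `reason`.
#' @export
select_initial_states <- function(spectrum, window, seed = NULL,
                                  weight = c("f_over_e", "f"),
                                  basis = c("mch", "diagonal")) {
  weight <- match.arg(weight)
  basis <- match.arg(basis)
  if (basis == "diagonal") {
    warning("initial-state selection in the diagonal basis; the delta-pulse ",
            "weights are only rigorous in the spin-free basis", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  if (any(spectrum$energy <= 0)) {
    stop("excitation energies must be positive", call. = FALSE)
  }
  spectrum <- dplyr::mutate(
    spectrum,
    w = ifelse(.data$energy >= window[1] & .data$energy <= window[2],
               if (weight == "f_over_e") .data$fosc / .data$energy
               else .data$fosc,
               0))
  totals <- dplyr::summarise(dplyr::group_by(spectrum, .data$sample),
                             total_weight = sum(.data$w), .groups = "drop")
  wmax <- max(totals$total_weight)
  out <- vector("list", nrow(totals))
  for (i in seq_len(nrow(totals))) {
    sid <- totals$sample[i]
    tw <- totals$total_weight[i]
    row <- list(sample = sid, accepted = FALSE, state = NA_integer_,
                total_weight = tw, reason = "")
    if (tw <= 0) {
      row$reason <- "no state in energy window"
    } else if (wmax > 0 && runif(1) < tw / wmax) {
      sub <- spectrum[spectrum$sample == sid & spectrum$w > 0, ]
      pick <- runif(1) * tw
      idx <- which(pick < cumsum(sub$w))[1]
      row$accepted <- TRUE
      row$state <- as.integer(sub$state[idx])
      row$reason <- "selected"
    } else {
      row$reason <- "rejected by ensemble-normalised weight"
    }
    out[[i]] <- tibble::as_tibble(row)
  }
  dplyr::bind_rows(out)
}
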