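#' Simulation settings
#'
#' Validated container for everything the per-trajectory driver needs.
#' Defaults follow common practice for this family of methods: a 0.5 fs
#' nuclear step, 25 electronic substeps, the local-diabatization propagator,
#' overlap-based phase tracking, fully transformed gradients, the
#' fewest-switches hopping formula, coupling-parallel velocity rescaling and
#' the energy-based decoherence correction with C = 0.1 hartree.
#'
#' @param dt Nuclear time step (a.u.; default 0.5 fs).
#' @param n_steps Number of nuclear steps.
#' @param n_substeps Electronic substeps per nuclear step (coupling-based
#'   propagator).
#' @param propagator `"ld"` (local diabatization, overlap-based) or `"nac"`
#'   (Hamiltonian + time-derivative couplings).
#' @param gradients `"full"` (transformed, with the coupling term),
#'   `"no-nac"` (transformed, coupling term omitted) or `"mch"` (gradient of
#'   the dominant spin-free character).
#' @param hop `"fs"` (propagator-based fewest-switches formula) or
#'   `"gfsh"` (global flux).
#' @param rescale `"nac-parallel"`, `"full-velocity"` or `"none"`.
#' @param reflect Reflect the parallel velocity component on frustrated
#'   hops?
#' @param decoherence `"edc"` or `"none"`.
#' @param decoherence_c Decoherence constant C (hartree).
#' @param tracking `"overlap"` (overlap-corrected phase tracking),
#'   `"projection"` (projection-only variant, known to misassign at
#'   simultaneous crossings; kept for comparison) or `"none"`.
#' @param deg_threshold Degeneracy threshold (hartree).
#' @param nac_threshold Spin-free near-degeneracy threshold for zeroing
#'   coupling elements (hartree).
#' @param laser A [laser_pulse()] or `NULL`.
#' @param laser_hop_tol Laser-hop energy tolerance (hartree); default 2x the
#'   pulse's spectral width (0.01 for a constant envelope).
#' @param seed Master seed; each trajectory derives its own stream from it
#'   and its index.
#' @param record_every Record every n-th step (step 0 and the last step are
#'   always recorded).
#' @param inject_phases Multiply the raw eigenvectors each step by random
#'   column phases and random unitary rotations within degenerate blocks
#'   (drawn from a separate stream) — a robustness harness; all observables
#'   must be invariant.
#' @param injection_seed Seed of the injection stream.
#' @param max_steps_lost Abort the trajectory if phase correspondence is
#'   flagged lost in more than this many consecutive steps (`Inf` to keep
#'   going).
#' @param energy_window Optional kill criterion: terminate the trajectory
#'   (status recorded) if the total energy deviates from its initial value
#'   by more than this many hartree (`Inf` to disable).
#' @return A `sim_settings` list.
#' @export
sim_settings <- function(dt = 0.5 * au_units$fs, n_steps = 100L,
                         n_substeps = 25L,
                         propagator = c("ld", "nac"),
                         gradients = c("full", "no-nac", "mch"),
                         hop = c("fs", "gfsh"),
                         rescale = c("nac-parallel", "full-velocity", "none"),
                         reflect = FALSE,
                         decoherence = c("edc", "none"),
                         decoherence_c = 0.1,
                         tracking = c("overlap", "projection", "none"),
                         deg_threshold = 1e-9, nac_threshold = 1e-8,
                         laser = NULL, laser_hop_tol = NULL,
                         seed = 1L, record_every = 1L,
                         inject_phases = FALSE, injection_seed = NULL,
                         max_steps_lost = Inf, energy_window = Inf) {
  stopifnot(dt > 0, n_steps >= 1)
  if (!is.null(laser) && !inherits(laser, "laser_pulse")) {
    stop("'laser' must be a laser_pulse or NULL", call. = FALSE)
  }
  if (is.null(laser_hop_tol) && !is.null(laser)) {
    laser_hop_tol <- if (laser$spectral_fwhm > 0) 2 * laser$spectral_fwhm
                     else 0.01
  }
  structure(list(
    dt = dt, n_steps = as.integer(n_steps),
    n_substeps = as.integer(n_substeps),
    propagator = match.arg(propagator), gradients = match.arg(gradients),
    hop = match.arg(hop), rescale = match.arg(rescale),
    reflect = isTRUE(reflect), decoherence = match.arg(decoherence),
    decoherence_c = decoherence_c, tracking = match.arg(tracking),
    deg_threshold = deg_threshold, nac_threshold = nac_threshold,
    laser = laser, laser_hop_tol = laser_hop_tol,
    seed = as.integer(seed), record_every = as.integer(record_every),
    inject_phases = isTRUE(inject_phases),
    injection_seed = injection_seed %||% 20111L,
    max_steps_lost = max_steps_lost, energy_window = energy_window
  ), class = "sim_settings")
}

#' One velocity-Verlet step
#'
#' \eqn{x' = x + v\Delta t - g\Delta t^2/(2m)};
#' \eqn{v' = v - (g + g')\Delta t/(2m)}, componentwise with per-coordinate
#' masses; `g` is the gradient (not the force) of the active surface.
#'
#' @param x,v Coordinates and velocities.
#' @param g,g_new Active-state gradient at the old and new geometry.
#' @param masses Per-coordinate masses.
#' @param dt Time step (a.u.).
#' @return List with `x` and `v` after the step.
#' @export
velocity_verlet_step <- function(x, v, g, g_new, masses, dt) {
  list(x = vv_position(x, v, g, masses, dt),
       v = vv_velocity(v, g, g_new, masses, dt))
}

vv_position <- function(x, v, g, masses, dt) {
  x + v * dt - g * dt^2 / (2 * masses)
}

vv_velocity <- function(v, g, g_new, masses, dt) {
  v - (g + g_new) * dt / (2 * masses)
}

# gradient of the active diagonal state under the configured scheme
active_gradient <- function(u, mch, active, settings) {
  switch(settings$gradients,
    full = transform_gradients(u, mch$gradients, mch$hamiltonian, mch$nacs,
                               include_nac_term = TRUE)[active, ],
    `no-nac` = transform_gradients(u, mch$gradients,
                                   include_nac_term = FALSE)[active, ],
    mch = mch$gradients[which.max(Mod(u[, active])^2), ]
  )
}

# coupling direction between two diagonal states (real part of the
# transformed coupling vector), for parallel rescaling
diag_nac_direction <- function(u, k_mch, a, b) {
  nm <- dim(k_mch)[3]
  out <- numeric(nm)
  for (i in seq_len(nm)) {
    out[i] <- Re(Conj(u[, a]) %*% k_mch[, , i] %*% u[, b])
  }
  out
}

# random unitary block-rotations + column phases for the injection harness
inject_random_phases <- function(u_raw, groups, seed) {
  n <- ncol(u_raw)
  with_temp_seed(seed, {
    d <- exp(2i * pi * runif(n))
    q <- diag(0i, n)
    for (g in groups) {
      m <- length(g)
      if (m == 1L) {
        q[g, g] <- 1
      } else {
        z <- matrix(complex(real = rnorm(m * m), imaginary = rnorm(m * m)),
                    m, m)
        qr_ <- qr(z)
        qm <- qr.Q(qr_)
        r <- diag(qr.R(qr_))
        q[g, g] <- qm %*% diag(r / Mod(r), m)
      }
    }
    u_raw %*% q %*% diag(d, n)
  })
}

#' Run a single surface-hopping trajectory
#'
#' The per-trajectory main loop. Each nuclear step performs, in order:
#' Verlet position update on the active surface; model evaluation at the new
#' geometry (plus laser coupling); wavefunction sign fixing from the overlap
#' matrix; diagonalization of the total Hamiltonian; phase tracking;
#' three-step propagation of the diagonal amplitudes; hopping probabilities
#' and the stochastic hop attempt with kinetic-energy adjustment;
#' decoherence correction; Verlet velocity update with the (possibly new)
#' active-state gradient.
#'
#' @param model A [vibronic_model()].
#' @param x0,v0 Initial coordinates and velocities.
#' @param state Initial electronic state index, or a complex amplitude
#'   vector over all states (normalised internally).
#' @param basis Basis of `state`: `"mch"` (spin-free; amplitudes transformed
#'   with \eqn{U(0)}, the active diagonal state is the one of maximal
#'   overlap) or `"diagonal"`.
#' @param active Explicit initial active diagonal state; default: the
#'   diagonal state of largest population.
#' @param settings A [sim_settings()].
#' @param traj_id Trajectory index (used for seeding and logs).
#' @param rng_seed Explicit RNG seed; default derived from
#'   `settings$seed` and `traj_id`.
#' @return An object of class `sh_trajectory` with per-step records (time,
#'   coordinates, velocities, active state, energies in both
#'   representations, amplitudes in both bases, total energy), the hop log,
#'   and a `status` field (`"ok"` or the failure reason — failed
#'   trajectories are returned, not dropped).
#' @export
run_trajectory <- function(model, x0, v0, state, basis = c("mch", "diagonal"),
                           settings = sim_settings(), traj_id = 1L,
                           rng_seed = NULL, active = NULL) {
  basis <- match.arg(basis)
  s <- settings
  rng_seed <- rng_seed %||% derive_seed(s$seed, traj_id)
  set.seed(rng_seed)
  n <- model$n_states
  nm <- model$n_modes
  masses <- model$masses
  nst <- s$n_steps

  mch <- evaluate_model(model, x0, prev = NULL,
                        nac_threshold = s$nac_threshold)
  mch_l <- couple_laser(mch, s$laser, 0)
  frame <- diagonalize_hamiltonian(mch_l$hamiltonian, s$deg_threshold)
  u <- frame$U
  if (s$inject_phases) {
    u <- inject_random_phases(u, frame$groups,
                              s$injection_seed + 131L * 0L + 7919L * traj_id)
    u <- track_phases(frame$U, u, s = NULL, energies = frame$energies,
                      deg_threshold = s$deg_threshold,
                      on_singular = "fallback")
    # at t = 0 tracking re-anchors the injected frame on the deterministic one
  }
  amp <- if (length(state) > 1) {
    z <- as.complex(state)
    z / sqrt(sum(Mod(z)^2))
  } else {
    z <- complex(n); z[state] <- 1; z
  }
  if (basis == "mch") {
    c_diag <- as.vector(Conj(t(u)) %*% amp)
    if (is.null(active)) {
      active <- if (length(state) > 1) which.max(Mod(c_diag)^2)
                else which.max(Mod(u[state, ])^2)
    }
  } else {
    c_diag <- amp
    if (is.null(active)) active <- which.max(Mod(c_diag)^2)
  }
  active <- as.integer(active)
  e_tr <- Re(diag(Conj(t(u)) %*% mch_l$hamiltonian %*% u))
  g_act <- active_gradient(u, mch_l, active, s)

  x <- as.numeric(x0); v <- as.numeric(v0)
  nrec <- nst + 1L
  rec <- list(
    time = numeric(nrec), x = matrix(0, nrec, nm), v = matrix(0, nrec, nm),
    active = integer(nrec), e_diag = matrix(0, nrec, n),
    e_mch = matrix(0, nrec, n), c_diag = matrix(0i, nrec, n),
    c_mch = matrix(0i, nrec, n), e_total = numeric(nrec),
    e_kin = numeric(nrec), lost = logical(nrec)
  )
  hops <- list()
  record <- function(k, tnow) {
    rec$time[k] <<- tnow
    rec$u_err[k] <<- max(Mod(Conj(t(u)) %*% u - diag(n)))
    rec$x[k, ] <<- x; rec$v[k, ] <<- v
    rec$active[k] <<- active
    rec$e_diag[k, ] <<- e_tr
    rec$e_mch[k, ] <<- mch$energies_sf
    rec$c_diag[k, ] <<- c_diag
    rec$c_mch[k, ] <<- as.vector(u %*% c_diag)
    ek <- sum(masses * v^2) / 2
    rec$e_kin[k] <<- ek
    rec$e_total[k] <<- ek + e_tr[active]
  }
  record(1L, 0)

  status <- "ok"
  consec_lost <- 0L
  step_done <- 0L
  res <- try(for (k in seq_len(nst)) {
    t_new <- k * s$dt
    # (1) position update on the active surface (kick-drift form: the
    # half-kicked velocity is what hops rescale, so a hop conserves
    # E_kin + E_active exactly at the new geometry)
    v_half <- v - g_act * s$dt / (2 * masses)
    x_new <- x + v_half * s$dt
    # (2) model evaluation (+ laser)
    mch_new <- evaluate_model(model, x_new, prev = mch,
                              nac_threshold = s$nac_threshold)
    # (3) sign fixing from the raw overlap, applied to all new-step matrices
    sf <- suppressWarnings(fix_wavefunction_signs(mch_new$overlap))
    mch_new <- apply_signs(mch_new, sf$signs)
    s_mch <- mch_new$overlap
    mch_new_l <- couple_laser(mch_new, s$laser, t_new)
    # (4) diagonalization
    frame_new <- diagonalize_hamiltonian(mch_new_l$hamiltonian,
                                         s$deg_threshold)
    u_raw <- frame_new$U
    if (s$inject_phases) {
      u_raw <- inject_random_phases(
        u_raw, frame_new$groups,
        s$injection_seed + 131L * k + 7919L * traj_id)
    }
    # (5) phase tracking
    u_new <- switch(s$tracking,
      overlap = track_phases(u, u_raw, s = s_mch,
                             energies = frame_new$energies,
                             deg_threshold = s$deg_threshold,
                             on_singular = "fallback"),
      projection = track_phases(u, u_raw, s = NULL,
                                energies = frame_new$energies,
                                deg_threshold = s$deg_threshold,
                                on_singular = "fallback"),
      none = u_raw)
    lost <- length(attr(u_new, "lost_states") %||% integer(0)) > 0
    consec_lost <- if (lost) consec_lost + 1L else 0L
    if (consec_lost > s$max_steps_lost) {
      stop("phase correspondence lost in ", consec_lost,
           " consecutive steps")
    }
    # (6) three-step propagation of the amplitudes
    p_mch <- if (s$propagator == "ld") {
      propagator_ld(mch_l$hamiltonian, mch_new_l$hamiltonian, s_mch, s$dt)
    } else {
      tmat_old <- time_derivative_coupling(mch, v)
      tmat_new <- time_derivative_coupling(mch_new, v_half)
      propagator_nac(mch_l$hamiltonian, mch_new_l$hamiltonian,
                     tmat_old, tmat_new, s$dt, s$n_substeps)
    }
    st <- step_coefficients(c_diag, u, u_new, p_mch)
    c_new <- st$c
    e_tr_new <- Re(diag(Conj(t(u_new)) %*% mch_new_l$hamiltonian %*% u_new))
    # (7) hopping
    h <- suppressWarnings(switch(s$hop,
      fs = hop_probabilities_fs(c_diag, c_new, st$p_diag, active),
      gfsh = hop_probabilities_gfsh(c_diag, c_new, active)))
    draw <- runif(1)   # drawn every step for reproducibility across options
    laser_on <- !is.null(s$laser) &&
      abs(s$laser$e0) * envelope_at(s$laser, t_new) > 1e-12
    cand <- which(draw < cumsum(h))[1]
    nacdir <- if (!is.na(cand) && s$rescale == "nac-parallel") {
      diag_nac_direction(u_new, mch_new$nacs, active, cand)
    } else NULL
    dec <- attempt_hop(h, draw, active, e_tr_new, v_half, masses,
                       mode = s$rescale, reflect = s$reflect,
                       nac_direction = nacdir,
                       laser_active = laser_on,
                       laser_omega = if (!is.null(s$laser)) s$laser$omega,
                       laser_tol = s$laser_hop_tol)
    if (dec$outcome %in% c("hop", "laser-hop")) active <- dec$candidate
    v_half <- dec$v_after
    if (dec$outcome != "no-hop") {
      hops[[length(hops) + 1L]] <- tibble::tibble(
        traj = traj_id, step = k, time = t_new, from = dec$old,
        to = dec$candidate, outcome = dec$outcome, delta_e = dec$delta_e,
        draw = draw,
        ekin_before = sum(masses * dec$v_before^2) / 2,
        ekin_after = sum(masses * dec$v_after^2) / 2,
        x = list(x_new))
    }
    # (8) decoherence
    if (s$decoherence == "edc") {
      c_new <- apply_decoherence_edc(c_new, active, e_tr_new,
                                     sum(masses * v_half^2) / 2,
                                     s$decoherence_c, s$dt)
    }
    # (9) second velocity half-kick with the (possibly new) active gradient
    g_new <- active_gradient(u_new, mch_new_l, active, s)
    v <- v_half - g_new * s$dt / (2 * masses)
    # shift caches
    x <- x_new; c_diag <- c_new; u <- u_new
    mch <- mch_new; mch_l <- mch_new_l
    e_tr <- e_tr_new; g_act <- g_new
    t_cur <- t_new
    step_done <- k
    record(k + 1L, t_new)
    rec$lost[k + 1L] <- lost
    if (abs(rec$e_total[k + 1L] - rec$e_total[1L]) > s$energy_window) {
      stop("total energy left the allowed window (deviation ",
           format(rec$e_total[k + 1L] - rec$e_total[1L]), " hartree)")
    }
  }, silent = TRUE)
  if (inherits(res, "try-error")) {
    status <- paste0("failed at step ", step_done + 1L, ": ",
                     conditionMessage(attr(res, "condition")))
    keep <- seq_len(step_done + 1L)
    rec <- lapply(rec, function(f) if (is.matrix(f)) f[keep, , drop = FALSE]
                                   else f[keep])
  }
  hops <- if (length(hops)) dplyr::bind_rows(hops) else empty_hop_log()
  structure(
    c(rec, list(hops = hops, status = status, settings = s,
                traj_id = traj_id, rng_seed = rng_seed,
                n_states = n, n_modes = nm, masses = masses)),
    class = "sh_trajectory"
  )
}

# T = v . K, real antisymmetric
time_derivative_coupling <- function(mch, v) {
  n <- nrow(mch$hamiltonian)
  tm <- matrix(0, n, n)
  for (i in seq_along(v)) tm <- tm + v[i] * mch$nacs[, , i]
  tm
}

#' @export
print.sh_trajectory <- function(x, ...) {
  cat("<sh_trajectory> ", length(x$time), " records, ", x$n_states,
      " states; status: ", x$status, "\n", sep = "")
  cat("  hops: ", sum(x$hops$outcome %in% c("hop", "laser-hop")),
      " accepted, ", sum(x$hops$outcome == "frustrated"), " frustrated\n",
      sep = "")
  invisible(x)
}

#' Tidy per-step records of a trajectory
#'
#' @param x An `sh_trajectory`.
#' @param ... Unused.
#' @return A tibble with one row per recorded step: time, active state,
#'   total/kinetic energy, and per-state diagonal populations in wide
#'   columns `pop_1 ... pop_n`.
#' @export
as_tibble.sh_trajectory <- function(x, ...) {
  pops <- Mod(x$c_diag)^2
  colnames(pops) <- paste0("pop_", seq_len(ncol(pops)))
  tibble::as_tibble(cbind(
    tibble::tibble(time = x$time, active = x$active,
                   e_total = x$e_total, e_kin = x$e_kin),
    tibble::as_tibble(pops)))
}

#' Run an ensemble of independent trajectories
#'
#' Each trajectory draws its random numbers from a stream derived from the
#' master seed and its index, so results are independent of execution order
#' and of which other trajectories are run.
#'
#' @param model A [vibronic_model()].
#' @param ics Initial conditions: a tibble with list-columns `x0`, `v0` and
#'   columns `state` and (optionally) `basis` — e.g. from
#'   [wigner_sample()] + [select_initial_states()] — or a plain list of
#'   lists with those fields.
#' @param settings A [sim_settings()].
#' @return An object of class `sh_ensemble` (a list of `sh_trajectory`
#'   objects with attributes).
#' @export
run_ensemble <- function(model, ics, settings = sim_settings()) {
  if (inherits(ics, "data.frame")) {
    ntraj <- nrow(ics)
    get_ic <- function(i) list(
      x0 = ics$x0[[i]], v0 = ics$v0[[i]], state = ics$state[[i]],
      basis = if ("basis" %in% names(ics)) ics$basis[[i]] else "mch",
      traj_id = if ("sample" %in% names(ics)) ics$sample[[i]] else i)
  } else {
    ntraj <- length(ics)
    get_ic <- function(i) {
      ic <- ics[[i]]
      ic$basis <- ic$basis %||% "mch"
      ic$traj_id <- ic$traj_id %||% i
      ic
    }
  }
  if (ntraj < 1) stop("need at least one initial condition", call. = FALSE)
  trajs <- vector("list", ntraj)
  for (i in seq_len(ntraj)) {
    ic <- get_ic(i)
    trajs[[i]] <- run_trajectory(model, ic$x0, ic$v0, ic$state, ic$basis,
                                 settings, traj_id = ic$traj_id)
  }
  structure(trajs, class = "sh_ensemble", settings = settings)
}

#' @export
print.sh_ensemble <- function(x, ...) {
  ok <- sum(vapply(x, function(tr) tr$status == "ok", logical(1)))
  cat("<sh_ensemble> ", length(x), " trajectories (", ok, " ok)\n", sep = "")
  invisible(x)
}
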