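test_that("velocity Verlet reproduces free and uniformly accelerated
           motion exactly", {
  st <- velocity_verlet_step(x = c(1, 2), v = c(0.1, -0.2),
                             g = c(0, 0), g_new = c(0, 0),
                             masses = c(1, 2), dt = 0.5)
  expect_equal(st$x, c(1.05, 1.9))
  expect_equal(st$v, c(0.1, -0.2))
  # constant gradient: exact kinematics x(t) = x0 + v t - g t^2 / (2m)
  g <- 0.3; mass <- 2; dt <- 0.1
  x <- 0; v <- 0
  for (k in 1:100) {
    st <- velocity_verlet_step(x, v, g, g, mass, dt)
    x <- st$x; v <- st$v
  }
  t_end <- 100 * dt
  expect_equal(x, -g * t_end^2 / (2 * mass), tolerance = 1e-12)
  expect_equal(v, -g * t_end / mass, tolerance = 1e-12)
})

test_that("velocity Verlet conserves energy and period on a harmonic
           oscillator", {
  omega <- 0.02; mass <- 1 / omega
  dt <- 2 * pi / omega / 100
  x <- 1.3; v <- 0
  xs <- numeric(1000); es <- numeric(1000)
  for (k in 1:1000) {
    g_old <- omega * x
    x_new <- x + v * dt - g_old * dt^2 / (2 * mass)
    st <- velocity_verlet_step(x, v, g_old, omega * x_new, mass, dt)
    x <- st$x; v <- st$v
    xs[k] <- x
    es[k] <- mass * v^2 / 2 + omega * x^2 / 2
  }
  e0 <- omega * 1.3^2 / 2
  expect_lt(max(abs(es - e0)) / e0, 1e-3)
  expect_lt(abs(es[1000] - e0) / e0, 1e-3)
  # period from the first return to positive-going zero crossing
  zc <- which(diff(sign(xs)) > 0)
  period <- diff(zc[1:2]) * dt
  expect_equal(period, 2 * pi / omega, tolerance = 1e-3)
})

test_that("a decoupled populated state never hops and conserves energy", {
  m <- lvc_model(omega = c(0.01, 0.02), multiplicities = c(1, 1),
                 epsilon = c(0, 0.2))
  tr <- run_trajectory(m, c(1.0, -0.5), c(0.005, 0.002), 1, "mch",
                       sim_settings(n_steps = 1000, seed = 9,
                                    decoherence = "none"))
  expect_identical(tr$status, "ok")
  expect_true(all(tr$active == tr$active[1]))
  expect_equal(nrow(tr$hops), 0L)
  expect_lt(diff(range(tr$e_total)), 1e-3)
  # secular drift (linear trend) far below the bounded oscillation
  drift <- unname(coef(lm(tr$e_total ~ seq_along(tr$e_total)))[2]) * 1000
  expect_lt(abs(drift), 1e-5)
})

test_that("identical settings and seed give bit-identical trajectories", {
  m <- lvc_isc_demo()
  s <- sim_settings(n_steps = 40, seed = 31)
  t1 <- run_trajectory(m, c(0.3, 0.2), c(0.002, -0.001), 2, "mch", s)
  t2 <- run_trajectory(m, c(0.3, 0.2), c(0.002, -0.001), 2, "mch", s)
  expect_identical(t1$x, t2$x)
  expect_identical(t1$c_diag, t2$c_diag)
  expect_identical(t1$active, t2$active)
  expect_identical(t1$hops, t2$hops)
})

test_that("complete population transfer at simultaneous degenerate
           crossings with overlap tracking; projection tracking
           misassigns", {
  m <- degenerate_crossing_model()
  x0 <- -8
  c0 <- complex(6)
  c0[mch_index_of(m, x0, 1)] <- sqrt(0.7)  # populated oscillator
  c0[mch_index_of(m, x0, 2)] <- sqrt(0.3)  # one distinct flat state
  s15 <- sim_settings(n_steps = 45, seed = 3, decoherence = "none",
                      rescale = "full-velocity", tracking = "overlap")
  tr <- run_trajectory(m, x0, 0, c0, "mch", s15)
  expect_identical(tr$status, "ok")
  hops <- tr$hops[tr$hops$outcome == "hop", ]
  expect_gte(nrow(hops), 2)   # two traversals of the multiplet
  # the oscillator amplitude follows its character completely: the active
  # state's population is the full 0.7 at every record
  act_pop <- Mod(tr$c_diag[cbind(seq_along(tr$time), tr$active)])^2
  expect_gt(min(act_pop) / 0.7, 0.999)
  # the populated flat state keeps its label and population; all other
  # states stay empty
  flat_label <- which.max(Mod(tr$c_diag[1, ])^2 *
                            (seq_len(6) != tr$active[1]))
  flat_pop <- Mod(tr$c_diag[, flat_label])^2
  expect_lt(max(abs(flat_pop - 0.3)), 1e-6)
  # remaining states: population *changes* below 1e-6 (the second
  # oscillator keeps its constant tiny admixture)
  rest0 <- sum(Mod(tr$c_diag[1, setdiff(seq_len(6),
                                        c(flat_label, tr$active[1]))])^2)
  rest <- vapply(seq_along(tr$time), function(k) {
    sum(Mod(tr$c_diag[k, setdiff(seq_len(6),
                                 c(flat_label, tr$active[k]))])^2)
  }, numeric(1))
  expect_lt(max(abs(rest - rest0)), 1e-6)

  # projection-only tracking: the flat-state population is misassigned
  s14 <- sim_settings(n_steps = 45, seed = 3, decoherence = "none",
                      rescale = "full-velocity", tracking = "projection")
  tr14 <- run_trajectory(m, x0, 0, c0, "mch", s14)
  flat_pop14 <- Mod(tr14$c_diag[, flat_label])^2
  expect_gt(max(abs(flat_pop14 - 0.3)), 0.25)
})

test_that("ensembles are independent of execution order and reduce to
           single runs", {
  m <- lvc_isc_demo()
  s <- sim_settings(n_steps = 25, seed = 17)
  ics <- tibble::tibble(
    sample = 1:3,
    x0 = list(c(0.3, 0.2), c(-0.2, 0.4), c(0.1, -0.1)),
    v0 = list(c(0.002, 0), c(0, 0.003), c(-0.001, 0.001)),
    state = 2, basis = "mch")
  ens <- run_ensemble(m, ics, s)
  solo <- run_trajectory(m, ics$x0[[2]], ics$v0[[2]], 2, "mch", s,
                         traj_id = 2L)
  expect_identical(ens[[2]]$c_diag, solo$c_diag)
  # permuted input: outputs permute identically
  ens_perm <- run_ensemble(m, ics[c(3, 1, 2), ], s)
  expect_identical(ens_perm[[2]]$x, ens[[1]]$x)
  expect_identical(ens_perm[[1]]$hops$draw, ens[[3]]$hops$draw)
})

test_that("spin-free-surface propagation matches diagonal propagation on a
           coupling-free model up to state relabeling", {
  # no constant coupling: U is a permutation, both modes see identical
  # surfaces
  m <- lvc_model(omega = c(0.012), multiplicities = c(1, 1),
                 epsilon = c(0, 0.08),
                 kappa = matrix(c(0.002, -0.003), 2, 1),
                 lambda = array(c(0, 0.002, 0.002, 0), c(2, 2, 1)))
  sd_ <- sim_settings(n_steps = 120, seed = 13, decoherence = "none",
                      gradients = "full")
  sm <- sim_settings(n_steps = 120, seed = 13, decoherence = "none",
                     gradients = "mch")
  td <- run_trajectory(m, 0.5, 0.004, 2, "mch", sd_)
  tm <- run_trajectory(m, 0.5, 0.004, 2, "mch", sm)
  expect_equal(td$x, tm$x, tolerance = 1e-8)
  expect_equal(td$e_total, tm$e_total, tolerance = 1e-8)
})

test_that("failed model evaluations terminate the trajectory with a
           recorded status", {
  m <- lvc_isc_demo()
  # poisoned evaluator: fails once the trajectory leaves a small region
  m_bad <- m
  class(m_bad) <- c("exploding_model", class(m))
  bad_eval <- function(model, x, ...) {
    if (max(abs(x)) > 0.5) stop("electronic structure failed")
    class(model) <- "vibronic_model"
    evaluate_model(model, x, ...)
  }
  registerS3method("evaluate_model", "exploding_model", bad_eval,
                   envir = asNamespace("hopdyn"))
  tr <- run_trajectory(m_bad, c(0.4, 0.2), c(0.002, 0), 2, "mch",
                       sim_settings(n_steps = 200, seed = 2))
  expect_match(tr$status, "failed at step")
  expect_lt(length(tr$time), 201)
  expect_gt(length(tr$time), 1)
})

test_that("the energy-window kill criterion terminates runaway
           trajectories with a recorded status", {
  m <- lvc_isc_demo()
  tr <- run_trajectory(m, c(0.3, 0.2), c(0.002, -0.001), 2, "mch",
                       sim_settings(n_steps = 200, seed = 7,
                                    decoherence = "none",
                                    energy_window = 1e-4))
  expect_match(tr$status, "energy left the allowed window")
  expect_lt(length(tr$time), 201)
})

test_that("a laser pulse drives population into the excited state", {
  mu <- 0.8
  w0 <- 0.1
  dx <- matrix(0i, 2, 2); dx[1, 2] <- dx[2, 1] <- mu
  m <- vibronic_model(omega = 0.01, epsilon = c(0, w0),
                      kappa = matrix(c(0, 0.001), 2, 1),
                      dipoles = list(dx, matrix(0i, 2, 2), matrix(0i, 2, 2)),
                      groups = list(1L, 2L))
  pulse <- laser_pulse(0.005, w0, polarization = c(1, 0, 0),
                       envelope = "gaussian", t0 = 400, fwhm = 300)
  s <- sim_settings(dt = 2, n_steps = 400, seed = 4, laser = pulse,
                    decoherence = "none", propagator = "nac",
                    n_substeps = 50)
  tr <- run_trajectory(m, 0, 0, 1, "mch", s)
  expect_identical(tr$status, "ok")
  pop2 <- Mod(tr$c_diag[, 2])^2
  expect_gt(max(pop2), 0.1)   # field moved population
  if (nrow(tr$hops)) {
    expect_true(all(tr$hops$outcome %in%
                      c("hop", "laser-hop", "frustrated")))
  }
})
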