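# a minimal synthetic trajectory object, good enough for the analysis layer
fake_traj <- function(times, active, c_diag, c_mch = c_diag, x = NULL,
                      hops = NULL, traj_id = 1L) {
  n <- ncol(c_diag)
  structure(list(
    time = times, x = x %||% matrix(0, length(times), 1),
    v = matrix(0, length(times), 1), active = active,
    e_diag = matrix(0, length(times), n),
    e_mch = matrix(0, length(times), n),
    c_diag = c_diag, c_mch = c_mch,
    e_total = numeric(length(times)), e_kin = numeric(length(times)),
    lost = logical(length(times)),
    hops = hops %||% hopdyn:::empty_hop_log(),
    status = "ok", settings = NULL, traj_id = traj_id, rng_seed = 1L,
    n_states = n, n_modes = 1L, masses = 1),
    class = "sh_trajectory")
}

test_that("amplitude and classical protocols agree for a pinned state", {
  times <- seq(0, 10, by = 1)
  cd <- matrix(0i, 11, 3); cd[, 1] <- 1
  tr <- fake_traj(times, active = rep(1L, 11), c_diag = cd)
  for (proto in c("a", "b")) {
    tab <- populations(list(tr), protocol = proto)
    wide <- tidyr::pivot_wider(tab, names_from = "state",
                               values_from = "population")
    expect_true(all(wide$`1` == 1))
    expect_true(all(wide$`2` == 0 & wide$`3` == 0))
  }
  # c_mch identical to c_diag (identity transformation): protocol c == a
  ta <- populations(list(tr), protocol = "a")
  tc <- populations(list(tr), protocol = "c")
  expect_equal(ta$population, tc$population)
})

test_that("population protocols conserve the total and b counts states", {
  set.seed(30)
  trajs <- lapply(1:6, function(i) {
    cd <- matrix(complex(real = rnorm(33), imaginary = rnorm(33)), 11, 3)
    cd <- cd / sqrt(rowSums(Mod(cd)^2))
    fake_traj(seq(0, 10), active = sample(1:3, 11, TRUE), cd,
              traj_id = i)
  })
  for (proto in c("a", "b", "c")) {
    tab <- populations(trajs, protocol = proto)
    tot <- dplyr::summarise(dplyr::group_by(tab, .data$time),
                            s = sum(.data$population))
    expect_lt(max(abs(tot$s - 1)), 1e-8)
  }
  # protocol b at t = 0 is the initial-state histogram
  tb <- populations(trajs, protocol = "b")
  h0 <- tabulate(vapply(trajs, function(tr) tr$active[1], integer(1)), 3) / 6
  expect_equal(tb$population[tb$time == 0], h0)
})

test_that("approximate spin-free counting matches exact counting when the
           transformation is a permutation", {
  # coupling-free two-state model: U is a permutation at every geometry
  m <- lvc_model(omega = 0.012, multiplicities = c(1, 1),
                 epsilon = c(0, 0.08), kappa = matrix(c(0.002, -0.003), 2, 1))
  s <- sim_settings(n_steps = 30, seed = 19, decoherence = "none")
  ens <- run_ensemble(m, tibble::tibble(sample = 1:2,
                                        x0 = list(0.4, -0.3),
                                        v0 = list(0.004, 0.002),
                                        state = 2, basis = "mch"), s)
  pb <- populations(ens, protocol = "b")
  pd <- populations(ens, protocol = "d", model = m)
  # the spin-free states are ordered by energy, which here matches the
  # diagonal ordering everywhere (no coupling, no crossing en route)
  expect_equal(pd$population, pb$population, tolerance = 1e-10)
})

test_that("quasi-diabatic projection reproduces diabatic populations on a
           coupling-free model", {
  m <- lvc_model(omega = 0.012, multiplicities = c(1, 1),
                 epsilon = c(0, 0.08), kappa = matrix(c(0.002, -0.003), 2, 1),
                 lambda = array(c(0, 0.002, 0.002, 0), c(2, 2, 1)))
  s <- sim_settings(n_steps = 20, seed = 23, decoherence = "none")
  ens <- run_ensemble(m, tibble::tibble(sample = 1, x0 = list(0.3),
                                        v0 = list(0.003), state = 2,
                                        basis = "mch"), s)
  pe <- populations(ens, protocol = "e", model = m, x_ref = 0)
  tot <- dplyr::summarise(dplyr::group_by(pe, .data$time),
                          s = sum(.data$population))
  expect_lt(max(abs(tot$s - 1)), 1e-8)
  expect_error(populations(ens, protocol = "e"), "reference")
})

test_that("histogram binning counts trajectories above a property
           threshold", {
  times <- seq(0, 5)
  t1 <- fake_traj(times, rep(1L, 6), matrix(1 + 0i, 6, 2) / sqrt(2))
  t2 <- fake_traj(times, rep(2L, 6), matrix(1 + 0i, 6, 2) / sqrt(2),
                  traj_id = 2L)
  tab <- populations(list(t1, t2), protocol = "f",
                     property = function(tr, k) tr$traj_id * 0.08,
                     threshold = 0.1)
  expect_true(all(tab$population == 0.5))
  expect_error(populations(list(t1), protocol = "f"), "threshold")
})

test_that("kinetic-model fitting recovers a known decay rate with
           honest bootstrap errors", {
  set.seed(77)
  k_true <- 0.01   # per a.u. time
  times <- seq(0, 400, by = 4)
  make_decay_traj <- function(i) {
    tau <- rexp(1, rate = k_true)
    act <- ifelse(times < tau, 1L, 2L)
    cd <- matrix(0i, length(times), 2)
    cd[cbind(seq_along(times), act)] <- 1
    fake_traj(times, act, cd, traj_id = i)
  }
  trajs <- lapply(1:200, make_decay_traj)
  tab <- populations(trajs, protocol = "b")
  net <- tibble::tibble(from = 1L, to = 2L)
  fit <- fit_kinetic_model(tab, net, n_bootstrap = 60, seed = 5)
  expect_lt(abs(fit$rates$rate - k_true) / k_true, 0.1)
  expect_true(fit$rates$ci_lower < k_true && k_true < fit$rates$ci_upper)
  td <- tidy(fit)
  expect_identical(td$term, "k_1->2")
  expect_true(glance(fit)$converged)
  # constant populations fit to (numerically) zero rates
  cd <- matrix(0i, length(times), 2); cd[, 1] <- 1
  flat <- lapply(1:20, function(i) fake_traj(times, rep(1L, length(times)),
                                             cd, traj_id = i))
  fit0 <- fit_kinetic_model(populations(flat, protocol = "b"), net,
                            n_bootstrap = 0)
  expect_lt(fit0$rates$rate, 1e-6)
})

test_that("bootstrap errors shrink roughly as one over the square root of
           the ensemble size", {
  set.seed(88)
  k_true <- 0.01
  times <- seq(0, 400, by = 8)
  make_decay_traj <- function(i) {
    tau <- rexp(1, rate = k_true)
    act <- ifelse(times < tau, 1L, 2L)
    cd <- matrix(0i, length(times), 2)
    cd[cbind(seq_along(times), act)] <- 1
    fake_traj(times, act, cd, traj_id = i)
  }
  trajs <- lapply(1:320, make_decay_traj)
  net <- tibble::tibble(from = 1L, to = 2L)
  se_small <- fit_kinetic_model(populations(trajs[1:80], protocol = "b"),
                                net, n_bootstrap = 40, seed = 1)$rates$se
  se_large <- fit_kinetic_model(populations(trajs, protocol = "b"),
                                net, n_bootstrap = 40, seed = 1)$rates$se
  ratio <- se_small / se_large
  expect_gt(ratio, 1.2)   # expected 2, allow sampling noise
  expect_lt(ratio, 3.5)
})

test_that("hop-geometry extraction matches an independent scan of the
           logs", {
  m <- lvc_isc_demo()
  s <- sim_settings(n_steps = 120, seed = 7, decoherence = "none")
  ens <- run_ensemble(m, tibble::tibble(sample = 1:3,
                                        x0 = list(c(0.3, 0.2), c(0.25, 0.3),
                                                  c(0.35, 0.1)),
                                        v0 = list(c(0.002, -0.001),
                                                  c(0, 0.002),
                                                  c(-0.001, 0)),
                                        state = 2, basis = "mch"), s)
  hg <- extract_hop_geometries(ens)
  expect_true(all(hg$outcome %in% c("hop", "laser-hop")))
  # dual-pass oracle: count accepted hops by scanning each log directly
  n_ref <- sum(vapply(ens, function(tr) {
    sum(tr$hops$outcome %in% c("hop", "laser-hop"))
  }, numeric(1)))
  expect_identical(nrow(hg), as.integer(n_ref))
  # pair filtering, both directions
  hg12 <- extract_hop_geometries(ens, from = 5, to = 2, directional = FALSE)
  n12 <- sum(vapply(ens, function(tr) {
    sum(tr$hops$outcome == "hop" &
          ((tr$hops$from == 5 & tr$hops$to == 2) |
             (tr$hops$from == 2 & tr$hops$to == 5)))
  }, numeric(1)))
  expect_identical(nrow(hg12), as.integer(n12))
  # a decoupled model yields an empty list
  m0 <- lvc_model(omega = 0.01, multiplicities = 1, epsilon = 0)
  ens0 <- run_ensemble(m0, tibble::tibble(sample = 1, x0 = list(0.5),
                                          v0 = list(0.001), state = 1,
                                          basis = "mch"),
                       sim_settings(n_steps = 30, seed = 1))
  expect_identical(nrow(extract_hop_geometries(ens0)), 0L)
})

test_that("internal coordinates follow the standard geometric
           definitions", {
  # 4 atoms; modes displace atom positions linearly
  ref <- c(0, 0, 0,  0, 0, 2.5,  0, 2, 2.5,  2, 2, 2.5)
  cmap <- list(ref = ref, modes = matrix(0, 12, 1),
               elements = c("C", "C", "O", "H"))
  m <- lvc_model(omega = 0.01, multiplicities = 1, epsilon = 0,
                 cartesian_map = cmap)
  tr <- fake_traj(c(0, 1), rep(1L, 2), matrix(1 + 0i, 2, 1))
  bond <- internal_coordinate(tr, list(type = "bond", atoms = c(1, 2)), m)
  expect_equal(bond$value, rep(2.5, 2))
  ang <- internal_coordinate(tr, list(type = "angle", atoms = c(1, 2, 3)), m)
  expect_equal(ang$value, rep(90, 2))
  # dihedral against an independently coded two-plane construction
  dih <- internal_coordinate(tr,
                             list(type = "dihedral", atoms = c(1, 2, 3, 4)),
                             m)
  pos <- matrix(ref, ncol = 3, byrow = TRUE)
  ref_dihedral <- function(p) {
    b1 <- p[2, ] - p[1, ]; b2 <- p[3, ] - p[2, ]; b3 <- p[4, ] - p[3, ]
    n1 <- c(b1[2] * b2[3] - b1[3] * b2[2], b1[3] * b2[1] - b1[1] * b2[3],
            b1[1] * b2[2] - b1[2] * b2[1])
    n2 <- c(b2[2] * b3[3] - b2[3] * b3[2], b2[3] * b3[1] - b2[1] * b3[3],
            b2[1] * b3[2] - b2[2] * b3[1])
    x <- sum(n1 * n2) * sqrt(sum(b2^2))
    y <- sum(c(n1[2] * n2[3] - n1[3] * n2[2],
               n1[3] * n2[1] - n1[1] * n2[3],
               n1[1] * n2[2] - n1[2] * n2[1]) * b2)
    atan2(y, x) * 180 / pi
  }
  expect_equal(dih$value[1], ref_dihedral(pos), tolerance = 1e-10)
  # collinear atoms: flagged undefined
  ref2 <- c(0, 0, 0,  0, 0, 1,  0, 0, 2,  1, 0, 2)
  m2 <- lvc_model(omega = 0.01, multiplicities = 1, epsilon = 0,
                  cartesian_map = list(ref = ref2,
                                       modes = matrix(0, 12, 1)))
  dih2 <- internal_coordinate(tr,
                              list(type = "dihedral",
                                   atoms = c(1, 2, 3, 4)), m2)
  expect_true(all(!dih2$defined))
  # raw model coordinate access
  md <- internal_coordinate(tr, list(type = "mode", mode = 1))
  expect_equal(md$value, tr$x[, 1])
})

test_that("random 4-atom dihedrals match the independent construction", {
  set.seed(41)
  tr <- fake_traj(0, 1L, matrix(1 + 0i, 1, 1))
  ref_dihedral <- function(p) {
    b1 <- p[2, ] - p[1, ]; b2 <- p[3, ] - p[2, ]; b3 <- p[4, ] - p[3, ]
    cross <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                              a[3] * b[1] - a[1] * b[3],
                              a[1] * b[2] - a[2] * b[1])
    n1 <- cross(b1, b2); n2 <- cross(b2, b3)
    atan2(sum(cross(n1, n2) * b2 / sqrt(sum(b2^2))), sum(n1 * n2)) * 180 / pi
  }
  for (rep in 1:10) {
    ref <- rnorm(12, sd = 2)
    m <- lvc_model(omega = 0.01, multiplicities = 1, epsilon = 0,
                   cartesian_map = list(ref = ref,
                                        modes = matrix(0, 12, 1)))
    dih <- internal_coordinate(tr,
                               list(type = "dihedral", atoms = 1:4), m)
    expect_equal(dih$value,
                 ref_dihedral(matrix(ref, ncol = 3, byrow = TRUE)),
                 tolerance = 1e-9)
  }
})
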