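# shared fixtures, built in code

# random small LVC model with SOC (n spin-free singlet-like states in one
# group unless multiplicities given)
random_lvc <- function(n_modes = 2, n_sf = 3, seed = 1, soc_scale = 5e-4,
                       multiplicities = rep(1, n_sf)) {
  set.seed(seed)
  omega <- runif(n_modes, 0.005, 0.02)
  epsilon <- sort(c(0, runif(n_sf - 1, 0.05, 0.2)))
  kappa <- matrix(rnorm(n_sf * n_modes, sd = 0.005), n_sf, n_modes)
  lambda <- array(0, c(n_sf, n_sf, n_modes))
  for (i in seq_len(n_modes)) {
    l <- matrix(rnorm(n_sf^2, sd = 0.002), n_sf, n_sf)
    l <- (l + t(l)) / 2
    diag(l) <- 0
    lambda[, , i] <- l
  }
  ntot <- sum(multiplicities)
  z <- matrix(complex(real = rnorm(ntot^2), imaginary = rnorm(ntot^2)),
              ntot, ntot) * soc_scale
  soc <- z + Conj(t(z))
  diag(soc) <- 0
  lvc_model(omega = omega, multiplicities = multiplicities,
            epsilon = epsilon, kappa = kappa, lambda = lambda, soc = soc)
}

random_unitary <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  z <- matrix(complex(real = rnorm(n * n), imaginary = rnorm(n * n)), n, n)
  qd <- qr(z)
  q <- qr.Q(qd)
  r <- diag(qr.R(qd))
  q %*% diag(r / Mod(r), n)
}

random_hermitian <- function(n, seed = NULL, scale = 1) {
  if (!is.null(seed)) set.seed(seed)
  z <- matrix(complex(real = rnorm(n * n), imaginary = rnorm(n * n)), n, n) *
    scale
  (z + Conj(t(z))) / 2
}

# time-derivative coupling matrix from an evaluation and a velocity
tdc <- function(mch, v) {
  n <- nrow(mch$hamiltonian)
  tm <- matrix(0, n, n)
  for (i in seq_along(v)) tm <- tm + v[i] * mch$nacs[, , i]
  tm
}

# amplitude vector concentrated on the spin-free state holding a given
# diabatic character of a model at a geometry
mch_index_of <- function(model, x, diabatic_state) {
  which.max(abs(evaluate_model(model, x)$W[diabatic_state, ]))
}

expect_unitary <- function(u, tol = 1e-10) {
  expect_lt(max(Mod(Conj(t(u)) %*% u - diag(ncol(u)))), tol)
}
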