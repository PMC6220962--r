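# Internal numerical helpers shared across modules.

# maximum absolute deviation from Hermiticity
hermiticity_error <- function(m) {
  max(Mod(m - Conj(t(m))))
}

assert_hermitian <- function(m, tol = 1e-8, what = "matrix") {
  if (nrow(m) != ncol(m)) {
    stop(what, " must be square", call. = FALSE)
  }
  err <- hermiticity_error(m)
  if (err > tol) {
    stop(what, " is not Hermitian (max deviation ", format(err), ")", call. = FALSE)
  }
  invisible(TRUE)
}

as_complex_matrix <- function(m) {
  if (is.complex(m)) return(m)
  matrix(complex(real = m), nrow = nrow(m), ncol = ncol(m))
}

# exp(-1i * H * tau) for Hermitian H, via eigendecomposition (exactly unitary
# up to roundoff; every propagator generator in this package is of this form)
unitary_exp <- function(h, tau) {
  h <- (h + Conj(t(h))) / 2
  e <- eigen(h, symmetric = TRUE)
  phases <- exp(-1i * e$values * tau)
  vec <- as_complex_matrix(e$vectors)
  vec %*% (phases * Conj(t(vec)))
}

# partition ascending energies into groups of near-degenerate states
degeneracy_groups <- function(energies, threshold = 1e-9) {
  n <- length(energies)
  if (n == 0L) return(list())
  brk <- which(diff(energies) > threshold)
  starts <- c(1L, brk + 1L)
  ends <- c(brk, n)
  purrr::map2(starts, ends, function(a, b) seq.int(a, b))
}

# run expr under a temporary RNG seed, restoring the caller's RNG state;
# used for phase-injection draws so the hopping stream is untouched
with_temp_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

# derive a per-trajectory seed below 2^31 from a master seed and an index
derive_seed <- function(master, index) {
  as.integer((as.numeric(master) %% 1e6) * 2011 + (index %% 1e5) * 7919 + 1) %% 2147483647L
}

# 31-bit polynomial rolling hash of a character vector, for provenance
# headers (content fingerprint, not cryptographic)
fnv1a <- function(x) {
  bytes <- utf8ToInt(paste(x, collapse = "\n"))
  h <- 17
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", h)
}

vapply_num <- function(x, f, ...) vapply(x, f, numeric(1), ...)

empty_hop_log <- function() {
  tibble::tibble(traj = integer(), step = integer(), time = numeric(),
                 from = integer(), to = integer(), outcome = character(),
                 delta_e = numeric(), draw = numeric(),
                 ekin_before = numeric(), ekin_after = numeric(),
                 x = list())
}
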