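#' Diagonalize a total electronic Hamiltonian
#'
#' Eigendecomposition of the (complex Hermitian) total Hamiltonian in the
#' spin-free basis, giving the diagonal representation: the surfaces on which
#' the nuclei are propagated. Eigenvalues are returned ascending; each
#' eigenvector's largest-magnitude component is made real and positive so the
#' raw output is deterministic (phase tracking handles continuity in time).
#'
#' @param h Complex Hermitian matrix (hartree).
#' @param deg_threshold Energy gap (hartree) below which consecutive
#'   eigenvalues are grouped as degenerate.
#' @param check_tol Maximum tolerated deviation from Hermiticity.
#' @return An object of class `diagonal_frame`: list with `U` (complex
#'   unitary, columns are eigenvectors), `energies` (ascending) and
#'   `groups` (degeneracy partition of the state indices).
#' @export
diagonalize_hamiltonian <- function(h, deg_threshold = 1e-9,
                                    check_tol = 1e-8) {
  assert_hermitian(h, check_tol, "hamiltonian")
  hh <- (h + Conj(t(h))) / 2
  e <- eigen(hh, symmetric = TRUE)
  idx <- order(e$values)
  u <- as_complex_matrix(as.matrix(e$vectors))[, idx, drop = FALSE]
  vals <- e$values[idx]
  for (j in seq_len(ncol(u))) {
    i <- which.max(Mod(u[, j]))
    ph <- u[i, j] / Mod(u[i, j])
    u[, j] <- u[, j] / ph
  }
  structure(list(U = u, energies = vals,
                 groups = degeneracy_groups(vals, deg_threshold),
                 deg_threshold = deg_threshold),
            class = "diagonal_frame")
}

#' @export
print.diagonal_frame <- function(x, ...) {
  cat("<diagonal_frame> ", length(x$energies), " states, ",
      length(x$groups), " degeneracy group(s)\n", sep = "")
  invisible(x)
}

#' Loewdin (symmetric) orthonormalization
#'
#' Returns the closest unitary matrix in Frobenius norm,
#' \eqn{A (A^\dagger A)^{-1/2}}, computed from the singular-value
#' decomposition (the unitary polar factor \eqn{U V^\dagger}), which is
#' stable also for nearly singular input.
#'
#' @param a Complex (or real) square nonsingular matrix.
#' @param tol Relative singular-value threshold below which the matrix is
#'   treated as singular.
#' @return Unitary matrix of the same dimension.
#' @export
loewdin_orthonormalize <- function(a, tol = 1e-12) {
  sv <- svd(a)
  if (min(sv$d) < tol * max(sv$d, 1e-300)) {
    stop("matrix is numerically singular (smallest singular value ",
         format(min(sv$d)), "); cannot orthonormalize", call. = FALSE)
  }
  sv$u %*% Conj(t(sv$v))
}

#' Remove random wavefunction signs using the overlap matrix
#'
#' Electronic-structure wavefunctions carry an arbitrary overall sign per
#' state and step. The overlap matrix with the previous step exposes sign
#' flips as negative dominant elements; this routine flips the affected
#' columns (new-step states) so matched overlaps are positive and returns the
#' sign vector, which must be applied consistently to every other matrix of
#' the new step.
#'
#' @param s_raw Real overlap matrix (rows: old states, columns: new states).
#' @param dominance Minimum magnitude of the dominant element for an
#'   unambiguous correspondence; columns without one keep sign +1 with a
#'   warning.
#' @return List with `S` (sign-fixed overlap) and `signs` (vector of +1/-1
#'   per new-step state).
#' @export
fix_wavefunction_signs <- function(s_raw, dominance = 0.5) {
  n <- ncol(s_raw)
  signs <- rep(1, n)
  ambiguous <- integer(0)
  for (j in seq_len(n)) {
    i <- which.max(abs(s_raw[, j]))
    if (abs(s_raw[i, j]) <= dominance) {
      ambiguous <- c(ambiguous, j)
    } else if (s_raw[i, j] < 0) {
      signs[j] <- -1
    }
  }
  if (length(ambiguous)) {
    warning("no dominant overlap for state(s) ",
            paste(ambiguous, collapse = ", "),
            "; keeping identity signs", call. = FALSE)
  }
  list(S = sweep(s_raw, 2, signs, "*"), signs = signs)
}

# apply a sign-fix vector to the matrices of the new step
apply_signs <- function(mch, signs) {
  if (all(signs == 1)) return(mch)
  d <- signs
  mch$hamiltonian <- d * t(d * t(mch$hamiltonian))
  for (i in seq_len(dim(mch$nacs)[3])) {
    mch$nacs[, , i] <- d * t(d * t(mch$nacs[, , i]))
  }
  mch$dipoles <- lapply(mch$dipoles, function(m) d * t(d * t(m)))
  mch$overlap <- sweep(mch$overlap, 2, d, "*")
  mch$W <- sweep(mch$W, 2, d, "*")
  mch
}

#' Track eigenvector phases across a time step
#'
#' Numerical diagonalization returns eigenvectors with arbitrary complex
#' phases (and arbitrary mixtures within degenerate blocks). To keep the
#' transformation matrix smooth in time, the raw eigenvectors of the new step
#' are re-phased/re-mixed — within degeneracy groups of the new Hamiltonian
#' only, so the result still diagonalizes it — to maximise continuity with
#' the previous step:
#' \deqn{U_{tracked} = U_{raw}\,[\hat O \hat C (U_{prev}^\dagger S\,
#'   U_{raw})]^\dagger}
#' where \eqn{S} is the spin-free overlap matrix between the steps (it
#' transforms away state crossings, including simultaneous multi-state
#' trivial crossings, before phases are matched), \eqn{\hat C} zeroes
#' elements between different degeneracy groups of the new spectrum and
#' \eqn{\hat O} Loewdin-orthonormalizes blockwise. With `S = NULL` the older
#' projection-only form \eqn{U_{raw}[\hat O \hat C(U_{prev}^\dagger
#' U_{raw})]^\dagger} is used; it misassigns phases when several states cross
#' simultaneously between two steps.
#'
#' @param u_prev Tracked transformation matrix of the previous step.
#' @param u_raw Raw eigenvector matrix of the new step.
#' @param s Real spin-free overlap matrix between the steps, or `NULL` for
#'   the projection-only fallback. It is sign-fixed and Loewdin-
#'   orthonormalized internally (finite-step overlaps are only approximately
#'   orthogonal).
#' @param energies Eigenvalues of the new step (ascending, matching
#'   `u_raw` columns).
#' @param deg_threshold Degeneracy threshold (hartree) for \eqn{\hat C}.
#' @param on_singular What to do when a diagonal block of the projected
#'   overlap is numerically singular (state correspondence lost across the
#'   step): `"error"` advises a smaller time step; `"fallback"` completes the
#'   lost directions with the SVD unitary (identity for fully dead blocks)
#'   and records them in the `"lost_states"` attribute.
#' @param singular_tol Singular values below this mark a lost direction.
#' @return The tracked unitary matrix, with attribute `lost_states`
#'   (integer vector, possibly empty).
#' @export
track_phases <- function(u_prev, u_raw, s = NULL, energies,
                         deg_threshold = 1e-9,
                         on_singular = c("error", "fallback"),
                         singular_tol = 0.1) {
  on_singular <- match.arg(on_singular)
  n <- ncol(u_raw)
  b <- if (is.null(s)) {
    Conj(t(u_prev)) %*% u_raw
  } else {
    sp <- loewdin_orthonormalize(fix_wavefunction_signs(s)$S)
    Conj(t(u_prev)) %*% sp %*% u_raw
  }
  groups <- degeneracy_groups(energies, deg_threshold)
  q <- matrix(0i, n, n)
  lost <- integer(0)
  for (g in groups) {
    bg <- b[g, g, drop = FALSE]
    sv <- svd(bg)
    dead <- sv$d < singular_tol
    if (any(dead)) {
      lost <- c(lost, g)
      if (on_singular == "error") {
        stop("state correspondence lost across the step for state(s) ",
             paste(g, collapse = ", "),
             "; use a smaller time step", call. = FALSE)
      }
      if (all(dead)) {
        q[g, g] <- diag(length(g))
        next
      }
    }
    q[g, g] <- sv$u %*% Conj(t(sv$v))
  }
  out <- u_raw %*% Conj(t(q))
  attr(out, "lost_states") <- lost
  out
}

#' Transform spin-free gradients to the diagonal representation
#'
#' The gradient of diagonal state \eqn{\alpha} is a linear combination of
#' spin-free gradients plus an energy-difference-scaled coupling term:
#' \deqn{g_\alpha^{diag} = \sum_\mu |U_{\mu\alpha}|^2 g_\mu +
#'   \sum_{\mu\neq\nu} U^*_{\mu\alpha} U_{\nu\alpha}
#'   (H_{\nu\nu} - H_{\mu\mu}) K_{\mu\nu}}
#' (with the coupling convention \eqn{K_{\mu\nu} =
#' \langle\mu|\partial_R|\nu\rangle}, so \eqn{(H_{\nu\nu} -
#' H_{\mu\mu})K_{\mu\nu}} is the off-diagonal derivative of the spin-free
#' Hamiltonian; the term reproduces the finite-difference eigenvalue
#' gradient wherever the transformation varies smoothly).
#' The second term matters near strong state mixing; it can be omitted
#' (`include_nac_term = FALSE`) when coupling vectors are unavailable, at the
#' price of degraded total-energy conservation.
#'
#' @param u Transformation matrix (columns: diagonal states).
#' @param g_mch `n_states x n_modes` spin-free gradients.
#' @param h_mch Total Hamiltonian in the spin-free basis (needed for the
#'   coupling term).
#' @param k_mch `n_states x n_states x n_modes` coupling array (needed for
#'   the coupling term).
#' @param include_nac_term Include the second sum?
#' @return `n_states x n_modes` matrix of diagonal-state gradients.
#' @export
transform_gradients <- function(u, g_mch, h_mch = NULL, k_mch = NULL,
                                include_nac_term = TRUE) {
  w2 <- Mod(u)^2
  out <- t(w2) %*% g_mch
  if (include_nac_term) {
    if (is.null(k_mch) || is.null(h_mch)) {
      stop("the coupling gradient term needs both 'h_mch' and 'k_mch'",
           call. = FALSE)
    }
    hd <- Re(diag(h_mch))
    dmat <- outer(hd, hd, function(a, b) b - a)   # H_nunu - H_mumu
    for (i in seq_len(dim(k_mch)[3])) {
      m <- dmat * k_mch[, , i]            # symmetric real
      out[, i] <- out[, i] + Re(diag(Conj(t(u)) %*% m %*% u))
    }
  }
  out
}
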