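#' Ensemble population time series
#'
#' Computes time-resolved electronic populations from an ensemble under one
#' of six protocols:
#' \describe{
#'   \item{a}{mean of the diagonal quantum populations
#'     \eqn{|c^{diag}_\alpha|^2} over trajectories;}
#'   \item{b}{fraction of trajectories whose active (classical) state is
#'     \eqn{\alpha};}
#'   \item{c}{mean of the spin-free quantum populations
#'     \eqn{|c^{MCH}_i|^2 = |\sum_\alpha U_{i\alpha} c^{diag}_\alpha|^2};}
#'   \item{d}{classical populations mapped approximately to the spin-free
#'     states: each trajectory distributes its active state over spin-free
#'     states with weights \eqn{|U_{i\alpha}|^2};}
#'   \item{e}{quasi-diabatic populations: spin-free amplitudes projected onto
#'     the states of a fixed reference geometry via model-provided overlaps
#'     (needs `model` and `x_ref`);}
#'   \item{f}{histogram binning: fraction of trajectories whose scalar
#'     `property(trajectory, step)` exceeds `threshold` (e.g. an
#'     oscillator strength above 0.1).}
#' }
#' Protocols a, b and c conserve the total population exactly (b as counts
#' over N).
#'
#' @param ensemble An `sh_ensemble` (or list of `sh_trajectory`). The
#'   trajectories must share `dt`; times are truncated to the common range.
#' @param protocol One of `"a"`–`"f"`.
#' @param model,x_ref Model and reference geometry for protocols d and e.
#' @param property,threshold Accessor `function(traj, step)` and threshold
#'   for protocol f.
#' @return A tibble (class `ensemble_populations`) in long form: `time`,
#'   `state`, `population`, plus attributes `protocol`, `n_traj`, and
#'   `traj_pops` (time x state x trajectory array, used by the bootstrap).
#' @export
populations <- function(ensemble, protocol = c("a", "b", "c", "d", "e", "f"),
                        model = NULL, x_ref = NULL,
                        property = NULL, threshold = NULL) {
  protocol <- match.arg(protocol)
  trajs <- Filter(function(tr) tr$status == "ok" || length(tr$time) > 1,
                  unclass(ensemble))
  if (!length(trajs)) stop("no usable trajectories", call. = FALSE)
  nrec <- min(vapply(trajs, function(tr) length(tr$time), integer(1)))
  times <- trajs[[1]]$time[seq_len(nrec)]
  n <- trajs[[1]]$n_states
  ntraj <- length(trajs)
  if (protocol == "e" && (is.null(model) || is.null(x_ref))) {
    stop("protocol 'e' needs a model and a reference geometry for the ",
         "reference overlaps", call. = FALSE)
  }
  if (protocol == "f" && (is.null(property) || is.null(threshold))) {
    stop("protocol 'f' needs a property accessor and a threshold",
         call. = FALSE)
  }
  ref_w <- if (protocol == "e") evaluate_model(model, x_ref)$W
  per_traj <- function(tr) {
    keep <- seq_len(nrec)
    switch(protocol,
      a = Mod(tr$c_diag[keep, , drop = FALSE])^2,
      b = {
        m <- matrix(0, nrec, n)
        m[cbind(keep, tr$active[keep])] <- 1
        m
      },
      c = Mod(tr$c_mch[keep, , drop = FALSE])^2,
      d = {
        # |U|^2 weights of the active diagonal state; U is recovered from
        # the stored amplitude pair only up to the active column, so the
        # driver stores c in both bases; reconstruct weights from the model
        m <- matrix(0, nrec, n)
        for (k in keep) {
          u <- traj_u(tr, model, k)
          m[k, ] <- Mod(u[, tr$active[k]])^2
        }
        m
      },
      e = {
        m <- matrix(0, nrec, n)
        for (k in keep) {
          w <- evaluate_model(model, tr$x[k, ])$W
          s_ref <- t(ref_w) %*% w
          m[k, ] <- Mod(s_ref %*% tr$c_mch[k, ])^2
        }
        m
      },
      f = {
        m <- matrix(0, nrec, n)
        for (k in keep) {
          val <- property(tr, k)
          m[k, 1] <- as.numeric(isTRUE(val > threshold))
        }
        m
      })
  }
  arr <- array(0, c(nrec, n, ntraj))
  for (j in seq_len(ntraj)) arr[, , j] <- per_traj(trajs[[j]])
  pm <- apply(arr, c(1, 2), mean)
  out <- tibble::tibble(
    time = rep(times, n),
    state = rep(seq_len(n), each = nrec),
    population = as.vector(pm))
  if (protocol == "f") out <- out[out$state == 1, ]
  attr(out, "protocol") <- protocol
  attr(out, "n_traj") <- ntraj
  attr(out, "traj_pops") <- arr
  class(out) <- c("ensemble_populations", class(out))
  out
}

# transformation matrix at a recorded step, re-derived from the model;
# protocols that need U re-evaluate the model at the stored geometry
traj_u <- function(tr, model, k) {
  if (is.null(model)) {
    stop("this protocol needs the model to recover the transformation ",
         "matrix at the stored geometries", call. = FALSE)
  }
  mch <- evaluate_model(model, tr$x[k, ])
  fr <- diagonalize_hamiltonian(mch$hamiltonian)
  # align to the stored amplitudes: the stored c_mch equals U c_diag
  fr$U
}

#' @export
autoplot.ensemble_populations <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$time / au_units$fs,
                               y = .data$population,
                               colour = factor(.data$state))) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time / fs", y = "population", colour = "state",
                  title = paste0("ensemble populations (protocol ",
                                 attr(object, "protocol"), ")")) +
    ggplot2::theme_minimal()
}

# population matrix (time x state) from the per-trajectory array for a
# subset of trajectory indices
pop_matrix <- function(arr, idx) apply(arr[, , idx, drop = FALSE], c(1, 2),
                                       mean)

#' Fit a first-order kinetic model to population data
#'
#' Fits the rate constants of a user-proposed reaction network (first-order
#' directed edges between electronic states) to an ensemble population
#' table. The model is \eqn{\dot P = A(k) P} with
#' \eqn{A_{ji} {+}{=} k_{i\to j}}, \eqn{A_{ii} {-}{=} \sum_j k_{i\to j}},
#' solved by the matrix exponential; rates (log-parameterised, hence
#' nonnegative) are least-squares fitted to all state populations jointly.
#' Standard errors come from a bootstrap over trajectories: resample
#' trajectories with replacement, rebuild the table, refit.
#'
#' @param table An `ensemble_populations` object (protocols a–d).
#' @param network Tibble/data.frame with integer columns `from` and `to`.
#' @param n_bootstrap Bootstrap replicates (default 200).
#' @param seed RNG seed for the bootstrap.
#' @return A `kinetic_fit` object: `rates` tibble (`from`, `to`, `rate`,
#'   `se`, CI bounds), `fitted` curve tibble, `sse`, convergence info.
#' @export
fit_kinetic_model <- function(table, network, n_bootstrap = 200,
                              seed = NULL) {
  arr <- attr(table, "traj_pops")
  if (is.null(arr)) {
    stop("the population table carries no per-trajectory data ",
         "(needed for the bootstrap)", call. = FALSE)
  }
  times <- sort(unique(table$time))
  n <- dim(arr)[2]
  ntraj <- dim(arr)[3]
  ne <- nrow(network)
  if (any(network$from == network$to)) {
    stop("self-edges are not allowed in the network", call. = FALSE)
  }
  ratemat <- function(k) {
    a <- matrix(0, n, n)
    for (e in seq_len(ne)) {
      a[network$to[e], network$from[e]] <- a[network$to[e], network$from[e]] + k[e]
      a[network$from[e], network$from[e]] <-
        a[network$from[e], network$from[e]] - k[e]
    }
    a
  }
  predict_pops <- function(k, p0) {
    a <- ratemat(k)
    out <- matrix(0, length(times), n)
    for (i in seq_along(times)) {
      out[i, ] <- as.numeric(Matrix::expm(a * times[i]) %*% p0)
    }
    out
  }
  fit_once <- function(pm) {
    p0 <- pm[1, ]
    obj <- function(lk) sum((predict_pops(exp(lk), p0) - pm)^2)
    k0 <- rep(1 / max(diff(range(times)), 1), ne)
    op <- if (ne == 1) {
      o <- stats::optimize(obj, interval = log(k0) + c(-12, 12), tol = 1e-10)
      list(par = o$minimum, value = o$objective, convergence = 0L)
    } else {
      optim(log(k0), obj, method = "Nelder-Mead",
            control = list(maxit = 2000, reltol = 1e-10))
    }
    list(k = exp(op$par), sse = op$value, convergence = op$convergence)
  }
  pm_full <- pop_matrix(arr, seq_len(ntraj))
  main <- fit_once(pm_full)
  boots <- NULL
  if (n_bootstrap > 0) {
    if (!is.null(seed)) set.seed(seed)
    boots <- matrix(0, n_bootstrap, ne)
    for (b in seq_len(n_bootstrap)) {
      idx <- sample.int(ntraj, ntraj, replace = TRUE)
      boots[b, ] <- fit_once(pop_matrix(arr, idx))$k
    }
  }
  se <- if (is.null(boots)) rep(NA_real_, ne) else apply(boots, 2, stats::sd)
  ci <- if (is.null(boots)) matrix(NA_real_, 2, ne) else
    apply(boots, 2, stats::quantile, probs = c(0.025, 0.975))
  # identifiability diagnostic: bootstrap rate correlations near +-1
  if (!is.null(boots) && ne > 1) {
    cc <- stats::cor(boots)
    if (any(abs(cc[upper.tri(cc)]) > 0.99)) {
      warning("some rate constants are nearly perfectly correlated across ",
              "bootstrap replicates; the network may be unidentifiable",
              call. = FALSE)
    }
  }
  fitted <- predict_pops(main$k, pm_full[1, ])
  structure(list(
    rates = tibble::tibble(from = network$from, to = network$to,
                           rate = main$k, se = se,
                           ci_lower = ci[1, ], ci_upper = ci[2, ]),
    fitted = tibble::tibble(time = rep(times, n),
                            state = rep(seq_len(n), each = length(times)),
                            population = as.vector(fitted)),
    data = table, sse = main$sse, convergence = main$convergence,
    n_traj = ntraj, n_bootstrap = n_bootstrap),
    class = "kinetic_fit")
}

#' @export
print.kinetic_fit <- function(x, ...) {
  cat("<kinetic_fit> ", nrow(x$rates), " rate(s), ", x$n_traj,
      " trajectories, sse = ", format(x$sse, digits = 4), "\n", sep = "")
  print(x$rates)
  invisible(x)
}

#' @export
tidy.kinetic_fit <- function(x, ...) {
  dplyr::mutate(x$rates,
                term = paste0("k_", .data$from, "->", .data$to),
                estimate = .data$rate, std.error = .data$se,
                .keep = "unused")
}

#' @export
glance.kinetic_fit <- function(x, ...) {
  tibble::tibble(sse = x$sse, n_traj = x$n_traj,
                 n_bootstrap = x$n_bootstrap,
                 converged = x$convergence == 0)
}

#' @export
autoplot.kinetic_fit <- function(object, ...) {
  ggplot2::ggplot(object$data,
                  ggplot2::aes(x = .data$time / au_units$fs,
                               y = .data$population,
                               colour = factor(.data$state))) +
    ggplot2::geom_point(size = 0.6, alpha = 0.6) +
    ggplot2::geom_line(data = object$fitted) +
    ggplot2::labs(x = "time / fs", y = "population", colour = "state") +
    ggplot2::theme_minimal()
}

#' Extract geometries at which hops occurred
#'
#' Scans the hop logs of an ensemble for accepted hops between a given state
#' pair (optionally directional) and returns the geometries.
#'
#' @param ensemble An `sh_ensemble` or list of trajectories.
#' @param from,to State indices; `NULL` matches any.
#' @param directional If `FALSE`, `from`/`to` match in either order.
#' @param include_frustrated Also return frustrated attempts.
#' @return Tibble with `traj`, `time`, `from`, `to`, `outcome` and a
#'   list-column `x` of coordinate vectors.
#' @export
extract_hop_geometries <- function(ensemble, from = NULL, to = NULL,
                                   directional = TRUE,
                                   include_frustrated = FALSE) {
  logs <- dplyr::bind_rows(lapply(unclass(ensemble), function(tr) tr$hops))
  if (!nrow(logs)) return(logs)
  keep <- logs$outcome %in%
    c("hop", "laser-hop", if (include_frustrated) "frustrated")
  if (!is.null(from) && !is.null(to) && !directional) {
    keep <- keep & ((logs$from == from & logs$to == to) |
                      (logs$from == to & logs$to == from))
  } else {
    if (!is.null(from)) keep <- keep & logs$from == from
    if (!is.null(to)) keep <- keep & logs$to == to
  }
  logs[keep, ]
}

#' Internal coordinate time series
#'
#' Evaluates a bond length, bond angle, dihedral angle or raw model
#' coordinate along a trajectory. Cartesian coordinates are obtained through
#' the model's linear `cartesian_map`; bond lengths in bohr, angles and
#' dihedrals in degrees (dihedral sign by the right-hand rule looking from
#' the second to the third atom). Frames with collinear atoms yield `NA`
#' with a flag.
#'
#' @param trajectory An `sh_trajectory`.
#' @param definition List with `type` (`"bond"`, `"angle"`, `"dihedral"`,
#'   `"mode"`), and `atoms` (2–4 atom indices) or `mode` (coordinate index).
#' @param model The model (for its `cartesian_map`); not needed for
#'   `type = "mode"`.
#' @return Tibble with `time`, `value`, `defined`.
#' @export
internal_coordinate <- function(trajectory, definition, model = NULL) {
  type <- definition$type
  nrec <- length(trajectory$time)
  if (type == "mode") {
    return(tibble::tibble(time = trajectory$time,
                          value = trajectory$x[, definition$mode],
                          defined = TRUE))
  }
  cmap <- model$cartesian_map
  if (is.null(cmap)) {
    stop("internal coordinates in Cartesian space need a model with a ",
         "'cartesian_map'", call. = FALSE)
  }
  atoms <- definition$atoms
  val <- rep(NA_real_, nrec)
  ok <- rep(TRUE, nrec)
  for (k in seq_len(nrec)) {
    cart <- cmap$ref + as.numeric(cmap$modes %*% trajectory$x[k, ])
    pos <- matrix(cart, ncol = 3, byrow = TRUE)
    r <- pos[atoms, , drop = FALSE]
    res <- switch(type,
      bond = geom_bond(r),
      angle = geom_angle(r),
      dihedral = geom_dihedral(r),
      stop("unknown coordinate type '", type, "'", call. = FALSE))
    val[k] <- res$value
    ok[k] <- res$defined
  }
  tibble::tibble(time = trajectory$time, value = val, defined = ok)
}

geom_bond <- function(r) {
  list(value = sqrt(sum((r[2, ] - r[1, ])^2)), defined = TRUE)
}

geom_angle <- function(r) {
  v1 <- r[1, ] - r[2, ]
  v2 <- r[3, ] - r[2, ]
  n1 <- sqrt(sum(v1^2)); n2 <- sqrt(sum(v2^2))
  if (n1 == 0 || n2 == 0) return(list(value = NA_real_, defined = FALSE))
  cosang <- sum(v1 * v2) / (n1 * n2)
  list(value = acos(pmin(pmax(cosang, -1), 1)) * 180 / pi, defined = TRUE)
}

geom_dihedral <- function(r) {
  b1 <- r[2, ] - r[1, ]
  b2 <- r[3, ] - r[2, ]
  b3 <- r[4, ] - r[3, ]
  n1 <- pracma_cross(b1, b2)
  n2 <- pracma_cross(b2, b3)
  if (sum(n1^2) < 1e-20 || sum(n2^2) < 1e-20) {
    return(list(value = NA_real_, defined = FALSE))
  }
  b2h <- b2 / sqrt(sum(b2^2))
  ang <- atan2(sum(pracma_cross(n1, n2) * b2h), sum(n1 * n2)) * 180 / pi
  list(value = ang, defined = TRUE)
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' @export
autoplot.sh_trajectory <- function(object, what = c("populations", "energy"),
                                   ...) {
  what <- match.arg(what)
  df <- as_tibble(object)
  if (what == "energy") {
    return(ggplot2::ggplot(df, ggplot2::aes(x = .data$time / au_units$fs,
                                            y = .data$e_total)) +
             ggplot2::geom_line() +
             ggplot2::labs(x = "time / fs", y = "total energy / hartree") +
             ggplot2::theme_minimal())
  }
  long <- tidyr::pivot_longer(df, dplyr::starts_with("pop_"),
                              names_to = "state", names_prefix = "pop_",
                              values_to = "population")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time / au_units$fs,
                                     y = .data$population,
                                     colour = .data$state)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time / fs", y = "population") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Turn a fitted object into a tidy tibble
#'
#' @param x A fitted object.
#' @param ... Passed on.
#' @export
tidy <- function(x, ...) UseMethod("tidy")

#' One-row model summary
#'
#' @param x A fitted object.
#' @param ... Passed on.
#' @export
glance <- function(x, ...) UseMethod("glance")
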