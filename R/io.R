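# Human-readable text dialects. All state-carrying numbers are serialized
# with 17 significant digits (round-trip exact for doubles); summary tables
# use 8. Every file starts with a format tag that readers verify.

fmt17 <- function(x) sprintf("%.17g", x)
fmt8 <- function(x) sprintf("%.8g", x)
num_line <- function(x) paste(fmt17(x), collapse = " ")
cplx_line <- function(z) paste(fmt17(rbind(Re(z), Im(z))), collapse = " ")
parse_nums <- function(line) as.numeric(strsplit(trimws(line), "\\s+")[[1]])
parse_cplx <- function(line) {
  v <- parse_nums(line)
  complex(real = v[c(TRUE, FALSE)], imaginary = v[c(FALSE, TRUE)])
}

check_format <- function(lines, tag) {
  hit <- grep(paste0("^format ", tag, " "), lines)
  if (!length(hit)) {
    stop("file does not carry the expected format tag '", tag, "'",
         call. = FALSE)
  }
  ver <- sub(paste0("^format ", tag, " "), "", lines[hit[1]])
  if (ver != "1") {
    stop("unsupported ", tag, " format version '", ver, "'", call. = FALSE)
  }
  invisible(TRUE)
}

# strip comments/blank lines; collapse runs of whitespace (parsers are
# insensitive to whitespace-only perturbations)
clean_lines <- function(lines) {
  lines <- sub("\r$", "", lines)
  lines <- trimws(lines)
  lines[nzchar(lines) & !startsWith(lines, "#")]
}

key_value <- function(lines, key, required = TRUE) {
  hit <- grep(paste0("^", key, "\\s"), lines)
  if (!length(hit)) {
    if (required) stop("missing key '", key, "'", call. = FALSE)
    return(NULL)
  }
  sub(paste0("^", key, "\\s+"), "", lines[hit[1]])
}

block_lines <- function(lines, name, n) {
  hit <- grep(paste0("^\\[", name, "\\]$"), lines)
  if (!length(hit)) stop("missing block [", name, "]", call. = FALSE)
  lines[(hit[1] + 1):(hit[1] + n)]
}

#' Write a vibronic model to a text parameter file
#'
#' Structured key/value + matrix-block dialect with units declared in the
#' header; [read_model()] round-trips it bit-identically.
#'
#' @param model A [vibronic_model()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  n <- model$n_states; nm <- model$n_modes
  out <- c(
    "# vibronic model parameter file; energies hartree, couplings hartree,",
    "# dipoles a.u.; coordinates dimensionless mass-frequency-weighted",
    "format hopdyn-model 1",
    paste("n_modes", nm),
    paste("n_states", n),
    "[omega]", num_line(model$omega),
    "[harmonic]", paste(as.integer(model$harmonic), collapse = " "),
    "[epsilon]", num_line(model$epsilon),
    "[masses]", num_line(model$masses),
    "[kappa]", apply(model$kappa, 1, num_line))
  for (i in seq_len(nm)) {
    out <- c(out, sprintf("[lambda_mode_%d]", i),
             apply(model$lambda[, , i, drop = FALSE], 1,
                   function(r) num_line(as.numeric(r))))
  }
  out <- c(out, "[soc]", apply(model$soc, 1, cplx_line))
  for (k in 1:3) {
    out <- c(out, sprintf("[dipole_%s]", c("x", "y", "z")[k]),
             apply(model$dipoles[[k]], 1, cplx_line))
  }
  out <- c(out, "[groups]",
           vapply(model$groups, function(g) paste(g, collapse = " "),
                  character(1)))
  writeLines(out, path)
  invisible(path)
}

#' Read a vibronic model parameter file
#'
#' @param path File written by [write_model()].
#' @return A [vibronic_model()].
#' @export
read_model <- function(path) {
  raw <- clean_lines(readLines(path))
  check_format(raw, "hopdyn-model")
  nm <- as.integer(key_value(raw, "n_modes"))
  n <- as.integer(key_value(raw, "n_states"))
  omega <- parse_nums(block_lines(raw, "omega", 1))
  harmonic <- as.logical(as.integer(
    strsplit(trimws(block_lines(raw, "harmonic", 1)), "\\s+")[[1]]))
  epsilon <- parse_nums(block_lines(raw, "epsilon", 1))
  masses <- parse_nums(block_lines(raw, "masses", 1))
  kappa <- do.call(rbind, lapply(block_lines(raw, "kappa", n), parse_nums))
  lambda <- array(0, c(n, n, nm))
  for (i in seq_len(nm)) {
    lambda[, , i] <- do.call(rbind, lapply(
      block_lines(raw, sprintf("lambda_mode_%d", i), n), parse_nums))
  }
  soc <- do.call(rbind, lapply(block_lines(raw, "soc", n), parse_cplx))
  dip <- lapply(c("x", "y", "z"), function(k) {
    do.call(rbind, lapply(block_lines(raw, paste0("dipole_", k), n),
                          parse_cplx))
  })
  gi <- grep("^\\[groups\\]$", raw)
  groups <- lapply(raw[(gi + 1):length(raw)],
                   function(l) as.integer(strsplit(l, "\\s+")[[1]]))
  vibronic_model(omega = omega, epsilon = epsilon, kappa = kappa,
                 lambda = lambda, harmonic = harmonic, soc = soc,
                 dipoles = dip, groups = groups, masses = masses)
}

#' Write initial conditions to a text file
#'
#' One block per sample (coordinates, velocities, selected state, weights).
#'
#' @param ics Tibble from [wigner_sample()] (optionally joined with a
#'   `state` column from [select_initial_states()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_initial_conditions <- function(ics, path) {
  out <- c("# initial conditions; coordinates dimensionless, velocities a.u.",
           "format hopdyn-ics 1",
           paste("n_samples", nrow(ics)))
  for (i in seq_len(nrow(ics))) {
    out <- c(out, sprintf("[sample %d]", ics$sample[[i]]),
             paste("x0", num_line(ics$x0[[i]])),
             paste("v0", num_line(ics$v0[[i]])),
             paste("sign_weight", fmt17(ics$sign_weight[[i]])))
    if ("state" %in% names(ics)) {
      out <- c(out, paste("state", ics$state[[i]]))
    }
  }
  writeLines(out, path)
  invisible(path)
}

#' Read an initial-conditions file
#'
#' @param path File written by [write_initial_conditions()].
#' @return Tibble with `sample`, list-columns `x0`, `v0`, `sign_weight` and
#'   (if present) `state`.
#' @export
read_initial_conditions <- function(path) {
  raw <- clean_lines(readLines(path))
  check_format(raw, "hopdyn-ics")
  starts <- grep("^\\[sample ", raw)
  ends <- c(starts[-1] - 1L, length(raw))
  rows <- purrr::map2(starts, ends, function(a, b) {
    blk <- raw[a:b]
    sid <- as.integer(sub("^\\[sample (\\d+)\\]$", "\\1", blk[1]))
    row <- tibble::tibble(
      sample = sid,
      x0 = list(parse_nums(key_value(blk, "x0"))),
      v0 = list(parse_nums(key_value(blk, "v0"))),
      sign_weight = as.numeric(key_value(blk, "sign_weight")))
    st <- key_value(blk, "state", required = FALSE)
    if (!is.null(st)) row$state <- as.integer(st)
    row
  })
  dplyr::bind_rows(rows)
}

#' Write a trajectory to a human-readable log file
#'
#' Append-only per-step blocks with all electronic and nuclear state
#' (17 significant digits), followed by the hop log. Round-trips through
#' [read_trajectory()] bit-identically.
#'
#' @param traj An `sh_trajectory`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  nrec <- length(traj$time)
  out <- c("# trajectory log; all quantities in atomic units",
           "format hopdyn-trajectory 1",
           paste("traj_id", traj$traj_id),
           paste("rng_seed", traj$rng_seed),
           paste("status", traj$status),
           paste("n_states", traj$n_states),
           paste("n_modes", traj$n_modes),
           paste("n_records", nrec),
           "[masses]", num_line(traj$masses))
  for (k in seq_len(nrec)) {
    out <- c(out, sprintf("[record %d]", k),
             paste("time", fmt17(traj$time[k])),
             paste("active", traj$active[k]),
             paste("x", num_line(traj$x[k, ])),
             paste("v", num_line(traj$v[k, ])),
             paste("e_diag", num_line(traj$e_diag[k, ])),
             paste("e_mch", num_line(traj$e_mch[k, ])),
             paste("e_total", fmt17(traj$e_total[k])),
             paste("e_kin", fmt17(traj$e_kin[k])),
             paste("c_diag", cplx_line(traj$c_diag[k, ])),
             paste("c_mch", cplx_line(traj$c_mch[k, ])))
  }
  out <- c(out, "[hops]", paste("n_hops", nrow(traj$hops)))
  if (nrow(traj$hops)) {
    for (i in seq_len(nrow(traj$hops))) {
      h <- traj$hops[i, ]
      out <- c(out, paste("hop", h$step, fmt17(h$time), h$from, h$to,
                          h$outcome, fmt17(h$delta_e), fmt17(h$draw),
                          fmt17(h$ekin_before), fmt17(h$ekin_after),
                          num_line(h$x[[1]])))
    }
  }
  writeLines(out, path)
  invisible(path)
}

#' Read a trajectory log file
#'
#' @param path File written by [write_trajectory()].
#' @return An `sh_trajectory` (without simulation settings, which are not
#'   part of the log dialect).
#' @export
read_trajectory <- function(path) {
  raw <- clean_lines(readLines(path))
  check_format(raw, "hopdyn-trajectory")
  n <- as.integer(key_value(raw, "n_states"))
  nm <- as.integer(key_value(raw, "n_modes"))
  nrec <- as.integer(key_value(raw, "n_records"))
  rec <- list(time = numeric(nrec), x = matrix(0, nrec, nm),
              v = matrix(0, nrec, nm), active = integer(nrec),
              e_diag = matrix(0, nrec, n), e_mch = matrix(0, nrec, n),
              c_diag = matrix(0i, nrec, n), c_mch = matrix(0i, nrec, n),
              e_total = numeric(nrec), e_kin = numeric(nrec),
              lost = logical(nrec))
  starts <- grep("^\\[record ", raw)
  for (k in seq_len(nrec)) {
    blk <- raw[starts[k]:(starts[k] + 10L)]
    rec$time[k] <- as.numeric(key_value(blk, "time"))
    rec$active[k] <- as.integer(key_value(blk, "active"))
    rec$x[k, ] <- parse_nums(key_value(blk, "x"))
    rec$v[k, ] <- parse_nums(key_value(blk, "v"))
    rec$e_diag[k, ] <- parse_nums(key_value(blk, "e_diag"))
    rec$e_mch[k, ] <- parse_nums(key_value(blk, "e_mch"))
    rec$e_total[k] <- as.numeric(key_value(blk, "e_total"))
    rec$e_kin[k] <- as.numeric(key_value(blk, "e_kin"))
    rec$c_diag[k, ] <- parse_cplx(key_value(blk, "c_diag"))
    rec$c_mch[k, ] <- parse_cplx(key_value(blk, "c_mch"))
  }
  hop_lines <- grep("^hop ", raw, value = TRUE)
  hops <- if (length(hop_lines)) {
    dplyr::bind_rows(lapply(hop_lines, function(l) {
      f <- strsplit(l, "\\s+")[[1]]
      tibble::tibble(traj = as.integer(key_value(raw, "traj_id")),
                     step = as.integer(f[2]), time = as.numeric(f[3]),
                     from = as.integer(f[4]), to = as.integer(f[5]),
                     outcome = f[6], delta_e = as.numeric(f[7]),
                     draw = as.numeric(f[8]),
                     ekin_before = as.numeric(f[9]),
                     ekin_after = as.numeric(f[10]),
                     x = list(as.numeric(f[-(1:10)])))
    }))
  } else {
    empty_hop_log()
  }
  structure(
    c(rec, list(hops = hops, status = key_value(raw, "status"),
                settings = NULL,
                traj_id = as.integer(key_value(raw, "traj_id")),
                rng_seed = as.integer(key_value(raw, "rng_seed")),
                n_states = n, n_modes = nm,
                masses = parse_nums(block_lines(raw, "masses", 1)))),
    class = "sh_trajectory")
}

#' Write an ensemble population table
#'
#' Tab-separated text, one column per state, with a header naming the
#' protocol; 8 significant digits (a human summary format).
#'
#' @param table An `ensemble_populations` tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_population_table <- function(table, path) {
  wide <- tidyr::pivot_wider(tibble::as_tibble(table),
                             names_from = "state", names_prefix = "state_",
                             values_from = "population")
  states <- setdiff(names(wide), "time")
  hdr <- c("# ensemble population table; time a.u.",
           "format hopdyn-populations 1",
           paste("protocol", attr(table, "protocol") %||% "a"),
           paste("n_traj", attr(table, "n_traj") %||% 0),
           paste(c("time", states), collapse = "\t"))
  body <- apply(wide, 1, function(r) paste(fmt8(as.numeric(r)),
                                           collapse = "\t"))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read an ensemble population table
#'
#' @param path File written by [write_population_table()].
#' @return An `ensemble_populations` tibble (no per-trajectory array).
#' @export
read_population_table <- function(path) {
  raw <- clean_lines(readLines(path))
  check_format(raw, "hopdyn-populations")
  protocol <- key_value(raw, "protocol")
  n_traj <- as.integer(key_value(raw, "n_traj"))
  hline <- grep("^time\t", raw)[1]
  cols <- strsplit(raw[hline], "\t")[[1]]
  body <- do.call(rbind, lapply(raw[-seq_len(hline)],
                                function(l) as.numeric(strsplit(l, "\t")[[1]])))
  colnames(body) <- cols
  wide <- tibble::as_tibble(body)
  out <- tidyr::pivot_longer(wide, -"time", names_to = "state",
                             names_prefix = "state_",
                             values_to = "population")
  out$state <- as.integer(out$state)
  out <- dplyr::arrange(out, .data$state, .data$time)
  attr(out, "protocol") <- protocol
  attr(out, "n_traj") <- n_traj
  class(out) <- c("ensemble_populations", class(out))
  out
}

#' Export a trajectory in XYZ format
#'
#' Standard XYZ dialect (count line, comment line, `element x y z` in
#' angstrom); requires the model to define a Cartesian map.
#'
#' @param traj An `sh_trajectory`.
#' @param model Model with a `cartesian_map` (including an `elements`
#'   character vector).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_xyz <- function(traj, model, path) {
  cmap <- model$cartesian_map
  if (is.null(cmap)) stop("the model defines no Cartesian map", call. = FALSE)
  natoms <- length(cmap$ref) / 3
  elements <- cmap$elements %||% rep("X", natoms)
  out <- character(0)
  for (k in seq_along(traj$time)) {
    cart <- (cmap$ref + as.numeric(cmap$modes %*% traj$x[k, ])) *
      au_units$angstrom
    pos <- matrix(cart, ncol = 3, byrow = TRUE)
    out <- c(out, as.character(natoms),
             sprintf("t= %s fs", fmt8(traj$time[k] / au_units$fs)),
             sprintf("%-3s %18.10f %18.10f %18.10f", elements,
                     pos[, 1], pos[, 2], pos[, 3]))
  }
  writeLines(out, path)
  invisible(path)
}
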