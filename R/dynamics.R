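#' Per-cell densities of a state vector
#'
#' The human density of cell `alpha` is the expectation of the number
#' operator, \eqn{n^{(a)}_\alpha = \langle\Psi, \hat n^{(a)}_\alpha \Psi
#' \rangle = \|a_\alpha \Psi\|^2}, i.e. the summed squared amplitude over
#' all basis states in which the mode is occupied; likewise for resources.
#' Densities therefore always lie in `[0, ||Psi||^2]`.
#'
#' @param psi Complex state vector of length `4^(L^2)`.
#' @param lattice An [lattice_spec()] object.
#' @return List with numeric vectors `n_a`, `n_b` of length `L^2`.
#' @export
densities_from_state <- function(psi, lattice) {
  stopifnot(inherits(lattice, "fp_lattice"))
  if (length(psi) != lattice$dim)
    stop("state vector has length ", length(psi), ", expected ",
         lattice$dim, call. = FALSE)
  w <- Re(psi * Conj(psi))
  M <- lattice$n_cells
  n_a <- numeric(M); n_b <- numeric(M)
  for (al in seq_len(M)) {
    n_a[al] <- sum(w[mode_bits(al, lattice) == 1L])
    n_b[al] <- sum(w[mode_bits(M + al, lattice) == 1L])
  }
  list(n_a = n_a, n_b = n_b)
}

new_trajectory <- function(time, n_a, n_b, norm, params, lattice_info,
                           dt, method, scenario = NA_character_,
                           seed = NA_integer_, status = "ok") {
  structure(
    list(time = time, n_a = n_a, n_b = n_b,
         global_a = rowSums(n_a), global_b = rowSums(n_b),
         norm = norm, params = params, lattice = lattice_info,
         dt = dt, method = method, scenario = scenario, seed = seed,
         status = status),
    class = "fp_trajectory")
}

#' @export
print.fp_trajectory <- function(x, ...) {
  cat(sprintf(
    "<fp_trajectory> %s | %d cells | t in [%g, %g] (%d samples, dt=%g) | %s\n",
    if (is.na(x$scenario)) x$method else x$scenario,
    ncol(x$n_a), min(x$time), max(x$time), length(x$time), x$dt, x$status))
  cat(sprintf("  global n_a: [%0.4f, %0.4f]   global n_a + n_b at t0: %0.6f\n",
              min(x$global_a), max(x$global_a),
              x$global_a[1] + x$global_b[1]))
  invisible(x)
}

#' Tidy data frame view of a trajectory
#'
#' One row per (time, series, species); the per-cell series carry
#' `cell_id` 1..n_cells and the lattice-wide sums carry `cell_id`
#' `"global"`.
#'
#' @param x An `fp_trajectory`.
#' @param ... Unused.
#' @return A `data.frame` with columns `time`, `cell_id`, `species`,
#'   `density`.
#' @export
as.data.frame.fp_trajectory <- function(x, ...) {
  M <- ncol(x$n_a); nt <- length(x$time)
  cells <- rep(seq_len(M), each = nt)
  df <- rbind(
    data.frame(time = rep(x$time, M), cell_id = as.character(cells),
               species = "a", density = as.vector(x$n_a)),
    data.frame(time = rep(x$time, M), cell_id = as.character(cells),
               species = "b", density = as.vector(x$n_b)),
    data.frame(time = x$time, cell_id = "global", species = "a",
               density = x$global_a),
    data.frame(time = x$time, cell_id = "global", species = "b",
               density = x$global_b))
  df[order(df$time, df$species, df$cell_id), , drop = FALSE]
}

#' Integrate the nonlinear Schrodinger dynamics on the full Fock space
#'
#' Advances \eqn{i\,\partial_t \Psi = H(\Psi)\,\Psi} with a fixed-step
#' 4th-order Runge-Kutta scheme, reassembling the Hamiltonian coefficients
#' from the instantaneous densities at every integrator stage (or once per
#' step with `coefficient_update = "step"`). The exact flow is
#' norm-preserving because `H` is Hermitian at each instant; the integrator
#' monitors the norm and aborts if it drifts beyond `norm_tol`, which
#' signals that `dt` is too large.
#'
#' @param psi0 Complex unit-norm state vector of length `4^(L^2)`.
#' @param params An [model_params()] object.
#' @param lattice An [lattice_spec()] object.
#' @param horizon Total integration time (dimensionless simulation units).
#' @param dt Time step (default `1e-3`).
#' @param record_every Record densities every this many steps.
#' @param method `"kernel"` (compiled fast path, default) or `"reference"`
#'   (pure-R integrator that reassembles the sparse Hamiltonian; only
#'   sensible for small lattices).
#' @param coefficient_update `"stage"` (default; faithful reading of the
#'   state-dependent dynamics) or `"step"` (coefficients frozen across the
#'   four stages of each step).
#' @param norm_tol Permitted absolute drift of `||Psi||` from 1.
#' @param coeff_override Reference method only: a list with numeric
#'   vectors `omega_a`, `omega_b`, `lambda` (per cell) and optionally
#'   `gamma` (per neighbour pair) that freezes the coefficients at these
#'   values for the whole run. Used for closed-form checks.
#' @return An `fp_trajectory`.
#' @export
evolve <- function(psi0, params, lattice, horizon, dt = 1e-3,
                   record_every = 10L,
                   method = c("kernel", "reference"),
                   coefficient_update = c("stage", "step"),
                   norm_tol = 1e-6, coeff_override = NULL) {
  stopifnot(inherits(params, "fp_params"), inherits(lattice, "fp_lattice"))
  method <- match.arg(method)
  coefficient_update <- match.arg(coefficient_update)
  if (horizon <= 0 || dt <= 0) stop("`horizon` and `dt` must be > 0", call. = FALSE)
  if (abs(sqrt(sum(Mod(psi0)^2)) - 1) > 1e-8)
    stop("`psi0` must be unit-norm", call. = FALSE)
  n_steps <- as.integer(round(horizon / dt))
  record_every <- max(1L, as.integer(record_every))
  if (method == "kernel") {
    if (!is.null(coeff_override))
      stop("`coeff_override` requires method = \"reference\"", call. = FALSE)
    pairs <- neighbor_pairs(lattice)
    res <- evolve_fock_cpp(as.complex(psi0), lattice$n_cells,
                           as.integer(pairs[, 1L]), as.integer(pairs[, 2L]),
                           params$sigma, params$tau, params$mu, params$p,
                           params$eps_density, dt, n_steps, record_every,
                           norm_tol, coefficient_update == "stage")
  } else {
    res <- evolve_reference(psi0, params, lattice, dt, n_steps,
                            record_every, norm_tol,
                            coefficient_update == "stage", coeff_override)
  }
  keep <- seq_len(res$n_recorded)
  traj <- new_trajectory(
    time = res$time[keep],
    n_a = res$n_a[keep, , drop = FALSE], n_b = res$n_b[keep, , drop = FALSE],
    norm = res$norm[keep], params = params,
    lattice_info = lattice, dt = dt, method = method, status = res$status)
  traj$psi_final <- res$psi_final
  if (res$status == "norm_drift")
    stop("norm drift exceeded norm_tol = ", norm_tol,
         " at t = ", max(traj$time),
         "; the step size dt is too large for this run", call. = FALSE)
  traj
}

# Pure-R RK4 on the full Fock space, reassembling the sparse Hamiltonian
# at every stage. Independent of the compiled kernel; used as its oracle.
evolve_reference <- function(psi0, params, lattice, dt, n_steps,
                             record_every, norm_tol, update_per_stage,
                             coeff_override = NULL) {
  terms <- hamiltonian_terms(lattice)
  M <- lattice$n_cells
  assemble <- function(psi) {
    if (!is.null(coeff_override)) {
      H <- coeff_override$omega_a[1L] * terms$N_a[[1L]]
      if (M > 1L) for (al in 2:M) H <- H + coeff_override$omega_a[al] * terms$N_a[[al]]
      for (al in seq_len(M)) {
        H <- H + coeff_override$omega_b[al] * terms$N_b[[al]]
        H <- H + coeff_override$lambda[al] * terms$X[[al]]
      }
      gam <- coeff_override$gamma
      if (!is.null(gam) && nrow(terms$pairs) > 0L)
        for (k in seq_len(nrow(terms$pairs)))
          H <- H + (params$p * gam[k]) * terms$M[[k]]
      return(H)
    }
    d <- densities_from_state(psi, lattice)
    assemble_hamiltonian(terms, d$n_a, d$n_b, params)
  }
  # real sparse H times complex vector, split into parts (Matrix has no
  # complex sparse classes)
  f <- function(psi, H)
    -1i * complex(real = as.vector(H %*% Re(psi)),
                  imaginary = as.vector(H %*% Im(psi)))
  n_rec <- n_steps %/% record_every + 1L
  rec_na <- matrix(NA_real_, n_rec, M); rec_nb <- matrix(NA_real_, n_rec, M)
  rec_t <- numeric(n_rec); rec_norm <- numeric(n_rec)
  snap <- function(i, psi, t) {
    d <- densities_from_state(psi, lattice)
    rec_na[i, ] <<- d$n_a; rec_nb[i, ] <<- d$n_b
    rec_t[i] <<- t; rec_norm[i] <<- sqrt(sum(Mod(psi)^2))
    rec_norm[i]
  }
  psi <- as.complex(psi0)
  snap(1L, psi, 0)
  irec <- 1L
  status <- "ok"
  H <- assemble(psi)
  for (step in seq_len(n_steps)) {
    H1 <- assemble(psi)
    k1 <- f(psi, H1)
    s2 <- psi + (dt / 2) * k1
    k2 <- f(s2, if (update_per_stage) assemble(s2) else H1)
    s3 <- psi + (dt / 2) * k2
    k3 <- f(s3, if (update_per_stage) assemble(s3) else H1)
    s4 <- psi + dt * k3
    k4 <- f(s4, if (update_per_stage) assemble(s4) else H1)
    psi <- psi + (dt / 6) * (k1 + 2 * k2 + 2 * k3 + k4)
    if (step %% record_every == 0L) {
      irec <- irec + 1L
      nrm <- snap(irec, psi, step * dt)
      if (abs(nrm - 1) > norm_tol) { status <- "norm_drift"; break }
    }
  }
  list(time = rec_t, n_a = rec_na, n_b = rec_nb, norm = rec_norm,
       n_recorded = irec, psi_final = psi, status = status)
}

#' Exact decoupled per-cell evolution (no-migration fast path)
#'
#' With the migration coupling switched off (`p = 0`) the Hamiltonian is a
#' sum of commuting single-cell terms and a per-cell product state evolves
#' with every cell confined to its own 4-dimensional space. This path
#' integrates each cell's 4 amplitudes directly, which is what makes runs
#' with hundreds or thousands of cells cheap.
#'
#' @param psi0_cells Complex `4 x n_cells` matrix of per-cell amplitudes in
#'   the local basis order `(00, 10, 01, 11)` (human bit first).
#' @inheritParams evolve
#' @return An `fp_trajectory`.
#' @export
evolve_percell <- function(psi0_cells, params, horizon, dt = 1e-3,
                           record_every = 10L,
                           coefficient_update = c("stage", "step"),
                           norm_tol = 1e-6) {
  stopifnot(inherits(params, "fp_params"))
  coefficient_update <- match.arg(coefficient_update)
  if (params$p != 0)
    stop("the per-cell fast path requires p = 0 (no migration)", call. = FALSE)
  if (!is.matrix(psi0_cells) || nrow(psi0_cells) != 4L)
    stop("`psi0_cells` must be a 4 x n_cells matrix", call. = FALSE)
  cell_norms <- sqrt(colSums(Mod(psi0_cells)^2))
  if (any(abs(cell_norms - 1) > 1e-8))
    stop("every per-cell state must be unit-norm", call. = FALSE)
  n_steps <- as.integer(round(horizon / dt))
  record_every <- max(1L, as.integer(record_every))
  M <- ncol(psi0_cells)
  res <- evolve_percell_cpp(psi0_cells, params$sigma, params$tau, params$mu,
                            params$eps_density, dt, n_steps, record_every,
                            norm_tol, coefficient_update == "stage")
  keep <- seq_len(res$n_recorded)
  lat_info <- list(L = NA_integer_, n_cells = M, n_modes = 2L * M,
                   dim = NA_real_, neighbors = "none", boundary = "none")
  traj <- new_trajectory(
    time = res$time[keep],
    n_a = res$n_a[keep, , drop = FALSE], n_b = res$n_b[keep, , drop = FALSE],
    norm = res$norm[keep], params = params, lattice_info = lat_info,
    dt = dt, method = "percell", status = res$status)
  traj$psi_final <- res$psi_final
  if (res$status == "norm_drift")
    stop("norm drift exceeded norm_tol = ", norm_tol,
         "; the step size dt is too large for this run", call. = FALSE)
  traj
}

#' Conservation and norm diagnostics of a trajectory
#'
#' The Hamiltonian commutes with the total number operator, so the global
#' human + resource density is conserved by the exact flow: any increase in
#' the global population density is mirrored by a decrease in the global
#' resource density. This check reports the maximum deviation of
#' `global n_a + global n_b` from its initial value and the maximum norm
#' deviation, and compares both against a tolerance.
#'
#' @param traj An `fp_trajectory`.
#' @param tol Tolerance for both deviations (default `1e-6`).
#' @return List with `max_conservation_dev`, `max_norm_dev`, `tol`, `pass`.
#' @export
conservation_check <- function(traj, tol = 1e-6) {
  stopifnot(inherits(traj, "fp_trajectory"))
  tot <- traj$global_a + traj$global_b
  dev <- max(abs(tot - tot[1L]))
  ndev <- max(abs(traj$norm - traj$norm[1L]))
  list(max_conservation_dev = dev, max_norm_dev = ndev, tol = tol,
       pass = dev <= tol && ndev <= tol)
}
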