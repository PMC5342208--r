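# run a piece of code with a locally seeded RNG, restoring global state
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Initialization specification
#'
#' Parameters of the initial-state protocol: per-cell human densities are
#' drawn uniformly within `jitter` of `K_total / n_cells`, rescaled so they
#' sum to `K_total` exactly (redrawing if the rescale leaves the band), and
#' the resource density of each cell is set complementarily to
#' `2 K_total / n_cells - n_a`, which places the system right at the
#' carrying capacity with `n_a + n_b = 2 K_total` globally.
#'
#' @param K_total Global carrying capacity (default `0.5`).
#' @param jitter Fractional spread of the per-cell draw (default `0.10`).
#' @param seed Integer RNG seed; same seed, same initial state.
#' @return An object of class `fp_init`.
#' @export
init_spec <- function(K_total = 0.5, jitter = 0.10, seed = 1L) {
  stopifnot(is.numeric(K_total), K_total > 0, K_total <= 1,
            is.numeric(jitter), jitter >= 0, jitter < 1,
            is.numeric(seed), length(seed) == 1L)
  structure(list(K_total = as.numeric(K_total), jitter = as.numeric(jitter),
                 seed = as.integer(seed)),
            class = "fp_init")
}

#' Jittered initial density field
#'
#' Draws the per-cell human densities of the initialization protocol and
#' returns them together with the complementary resource densities.
#'
#' @param spec An [init_spec()] object.
#' @param n_cells Number of lattice cells.
#' @return List with numeric vectors `n_a`, `n_b`; `sum(n_a)` equals
#'   `K_total` exactly and each `n_a` lies within the jitter band around
#'   `K_total / n_cells`.
#' @export
initial_densities <- function(spec, n_cells) {
  stopifnot(inherits(spec, "fp_init"))
  target <- spec$K_total / n_cells
  lo <- (1 - spec$jitter) * target
  hi <- (1 + spec$jitter) * target
  if (hi > 1 || 2 * target - lo > 1)
    stop("infeasible initialization: per-cell densities would exceed 1",
         call. = FALSE)
  n_a <- with_seed(spec$seed, {
    for (attempt in 1:1000) {
      x <- stats::runif(n_cells, lo, hi)
      x <- x * (spec$K_total / sum(x))
      if (all(x >= lo) && all(x <= hi)) break
    }
    x
  })
  # exact global condition despite floating point
  n_a <- n_a * (spec$K_total / sum(n_a))
  n_b <- 2 * target - n_a
  if (any(n_b < 0) || any(n_b > 1))
    stop("infeasible initialization: resource densities outside [0, 1]",
         call. = FALSE)
  list(n_a = n_a, n_b = n_b)
}

# per-cell amplitudes (00, 10, 01, 11) realizing densities (n_a, n_b) as a
# real, unentangled product within the cell
cell_amplitudes <- function(n_a, n_b) {
  rbind(sqrt((1 - n_a) * (1 - n_b)),
        sqrt(n_a * (1 - n_b)),
        sqrt((1 - n_a) * n_b),
        sqrt(n_a * n_b))
}

#' Initial state vectors
#'
#' `initial_state_percell()` returns the `4 x n_cells` matrix of real
#' nonnegative per-cell amplitudes realizing the drawn densities.
#' `initial_state()` builds the corresponding state on the full Fock
#' space by applying the per-cell creation-operator polynomial
#' \eqn{\prod_\alpha (c_{00} + c_{10} a_\alpha^\dagger + c_{01}
#' b_\alpha^\dagger + c_{11} a_\alpha^\dagger b_\alpha^\dagger)} to the
#' vacuum, in increasing cell order. Building the state through the
#' operators (rather than assigning tensor-product amplitudes directly)
#' keeps the fermionic sign structure consistent with the ladder-operator
#' convention, so the no-migration dynamics decouples exactly into the
#' per-cell picture.
#'
#' @param spec An [init_spec()] object.
#' @param lattice An [lattice_spec()] object.
#' @return `initial_state()`: a unit-norm complex vector of length
#'   `4^(L^2)`; `initial_state_percell()`: a complex `4 x n_cells` matrix.
#' @export
initial_state <- function(spec, lattice) {
  stopifnot(inherits(spec, "fp_init"), inherits(lattice, "fp_lattice"))
  d <- initial_densities(spec, lattice$n_cells)
  amp <- cell_amplitudes(d$n_a, d$n_b)
  psi <- numeric(lattice$dim)          # amplitudes stay real throughout
  psi[1L] <- 1
  for (al in seq_len(lattice$n_cells)) {
    Ad <- ladder_operator("a", al, dagger = TRUE, lattice = lattice)
    Bd <- ladder_operator("b", al, dagger = TRUE, lattice = lattice)
    psi <- amp[1L, al] * psi +
      amp[2L, al] * as.vector(Ad %*% psi) +
      amp[3L, al] * as.vector(Bd %*% psi) +
      amp[4L, al] * as.vector(Ad %*% (Bd %*% psi))
  }
  complex(real = psi / sqrt(sum(psi^2)))
}

#' @rdname initial_state
#' @param n_cells Number of cells (for the per-cell variant, which needs no
#'   lattice geometry).
#' @export
initial_state_percell <- function(spec, n_cells) {
  stopifnot(inherits(spec, "fp_init"))
  d <- initial_densities(spec, n_cells)
  amp <- cell_amplitudes(d$n_a, d$n_b)
  matrix(complex(real = amp), nrow = 4L, ncol = n_cells)
}

#' Run a named scenario
#'
#' Orchestrates the two study scenarios. `"no_migration"` forces `p = 0`
#' and uses the exact decoupled per-cell fast path (the initial state is a
#' per-cell product, so the decoupling is exact); it accepts a plain cell
#' count in place of a lattice, which allows runs with hundreds or
#' thousands of cells. `"migration"` integrates the full Fock-space
#' dynamics on the given lattice.
#'
#' @param name `"no_migration"` or `"migration"`.
#' @param params An [model_params()] object; for `"no_migration"` its `p`
#'   is overridden to 0, for `"migration"` it must be positive.
#' @param lattice An [lattice_spec()] object, or (no-migration only) a
#'   positive integer number of cells.
#' @param init An [init_spec()] object.
#' @param horizon,dt,record_every Integration settings (see [evolve()]).
#' @param ... Passed on to [evolve()] / [evolve_percell()].
#' @return An `fp_trajectory` with `scenario` and `seed` metadata set.
#' @export
run_scenario <- function(name = c("no_migration", "migration"), params,
                         lattice, init, horizon = 25, dt = 1e-3,
                         record_every = 20L, ...) {
  name <- match.arg(name)
  stopifnot(inherits(params, "fp_params"), inherits(init, "fp_init"))
  n_cells <- if (inherits(lattice, "fp_lattice")) lattice$n_cells
             else as.integer(lattice)
  if (name == "no_migration") {
    p0 <- params; p0$p <- 0
    psi0 <- initial_state_percell(init, n_cells)
    traj <- evolve_percell(psi0, p0, horizon = horizon, dt = dt,
                           record_every = record_every, ...)
  } else {
    if (!inherits(lattice, "fp_lattice"))
      stop("the migration scenario needs a full `lattice_spec()`", call. = FALSE)
    if (params$p <= 0)
      stop("the migration scenario needs p > 0; use \"no_migration\" for p = 0",
           call. = FALSE)
    psi0 <- initial_state(init, lattice)
    traj <- evolve(psi0, params, lattice, horizon = horizon, dt = dt,
                   record_every = record_every, ...)
  }
  traj$scenario <- name
  traj$seed <- init$seed
  traj
}

#' Parameter sweep over one axis
#'
#' Reruns a scenario while varying one model parameter over a grid, with
#' one or more replicate seeds per value, and summarizes the oscillation
#' statistics of every run.
#'
#' @param axis One of `"p"`, `"mu"`, `"tau"`, `"sigma"`.
#' @param values Numeric vector of parameter values to sweep.
#' @param seeds Integer vector of replicate seeds.
#' @param params Base [model_params()].
#' @param lattice Lattice (or cell count when every value of `p` is 0).
#' @param init Base [init_spec()]; its seed is replaced by each sweep seed.
#' @param horizon,dt,record_every Integration settings.
#' @param transient Initial fraction of the horizon excluded from the
#'   summary statistics (see [oscillation_interval()]).
#' @param ... Passed to [run_scenario()].
#' @return List with `runs` (list of `fp_trajectory`) and `summary`
#'   (data.frame: axis value, seed, min/max ratio, std ratio, amplitude,
#'   major peak/valley counts).
#' @export
parameter_sweep <- function(axis = c("p", "mu", "tau", "sigma"), values,
                            seeds = 1L, params = model_params(), lattice,
                            init = init_spec(), horizon = 25, dt = 1e-3,
                            record_every = 20L, transient = 0.05, ...) {
  axis <- match.arg(axis)
  stopifnot(is.numeric(values), length(values) >= 1L)
  runs <- list()
  rows <- list()
  for (v in values) {
    pv <- params
    pv[[axis]] <- v
    scen <- if (axis == "p" && v == 0) "no_migration"
            else if (pv$p > 0) "migration" else "no_migration"
    for (s in seeds) {
      iv <- init; iv$seed <- as.integer(s)
      tr <- run_scenario(scen, pv, lattice, iv, horizon = horizon, dt = dt,
                         record_every = record_every, ...)
      key <- sprintf("%s=%g_seed=%d", axis, v, as.integer(s))
      runs[[key]] <- tr
      osc <- oscillation_interval(tr, transient = transient)
      ext <- count_extremes(tr, transient = transient)
      rows[[key]] <- data.frame(
        axis = axis, value = v, seed = as.integer(s), scenario = scen,
        min_ratio = osc$min_ratio, max_ratio = osc$max_ratio,
        std_ratio = osc$std_ratio,
        amplitude = osc$max_ratio - osc$min_ratio,
        n_major_peaks = ext[["n_major_peaks"]],
        n_major_valleys = ext[["n_major_valleys"]])
    }
  }
  list(runs = runs, summary = do.call(rbind, c(rows, make.row.names = FALSE)))
}
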