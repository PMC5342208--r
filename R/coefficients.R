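#' Model parameters
#'
#' Collects the scalar parameters of the density-dependent Hamiltonian and
#' checks their domains. The defaults are the values used to reproduce the
#' South American demographic reconstruction: `sigma = 12.5`, `tau = 0.35`,
#' `mu = 0.25`, `p = 1`, `K_total = 0.5`, 10% initial jitter.
#'
#' @param sigma Strictly positive interaction-strength scale
#'   \eqn{\sigma_\alpha}.
#' @param tau Strictly positive ratio-sensitivity scale \eqn{\tau_\alpha}.
#' @param mu Nonnegative baseline predator-prey interaction
#'   \eqn{\mu_\alpha}; keeps a minimal exchange alive when both
#'   \eqn{\omega} terms vanish.
#' @param p Nonnegative migration coupling \eqn{p_{\alpha\beta}} applied to
#'   every neighbouring cell pair; `p = 0` is the no-migration scenario.
#' @param K_total Global carrying capacity `K` in `(0, 1]`: the conserved
#'   mean `(n_a + n_b)/2` around which the global human density oscillates.
#' @param jitter Fractional spread of the initial per-cell human densities
#'   around `K/L^2` (default `0.10`).
#' @param eps_density Small positive floor used when forming the local
#'   resource/human ratio, making the coefficient functions total.
#'
#' @return An object of class `fp_params` (a validated named list).
#' @examples
#' model_params()             # paper-default parameter set
#' model_params(p = 0)        # no-migration variant
#' @export
model_params <- function(sigma = 12.5, tau = 0.35, mu = 0.25, p = 1,
                         K_total = 0.5, jitter = 0.10, eps_density = 1e-10) {
  chk <- function(x, nm, lo, lo_open = TRUE) {
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
      stop("`", nm, "` must be a finite number", call. = FALSE)
    if (if (lo_open) x <= lo else x < lo)
      stop("`", nm, "` must be ", if (lo_open) "> " else ">= ", lo,
           call. = FALSE)
    as.numeric(x)
  }
  sigma <- chk(sigma, "sigma", 0)
  tau   <- chk(tau, "tau", 0)
  mu    <- chk(mu, "mu", 0, lo_open = FALSE)
  p     <- chk(p, "p", 0, lo_open = FALSE)
  K_total <- chk(K_total, "K_total", 0)
  if (K_total > 1) stop("`K_total` must be in (0, 1]", call. = FALSE)
  jitter <- chk(jitter, "jitter", 0, lo_open = FALSE)
  if (jitter >= 1) stop("`jitter` must be in [0, 1)", call. = FALSE)
  eps_density <- chk(eps_density, "eps_density", 0)
  structure(list(sigma = sigma, tau = tau, mu = mu, p = p,
                 K_total = K_total, jitter = jitter,
                 eps_density = eps_density),
            class = "fp_params")
}

#' @export
print.fp_params <- function(x, ...) {
  cat(sprintf(
    "<fp_params> sigma=%g tau=%g mu=%g p=%g K=%g jitter=%g eps=%g\n",
    x$sigma, x$tau, x$mu, x$p, x$K_total, x$jitter, x$eps_density))
  invisible(x)
}

#' Local resource/human density ratio
#'
#' \eqn{K_\alpha = n^{(b)}_\alpha / n^{(a)}_\alpha}, the quantity that
#' drives every Hamiltonian coefficient. Both densities are floored at
#' `eps` so the ratio is always finite and positive; in paper-regime runs
#' the floor is never reached.
#'
#' @param n_a,n_b Human and resource densities in `[0, 1]` (vectorized).
#' @param eps Positive density floor.
#' @return `max(n_b, eps) / max(n_a, eps)`, finite and `> 0`.
#' @examples
#' ratio_K(0.05, 0.10)  # 2
#' @export
ratio_K <- function(n_a, n_b, eps = 1e-10) {
  if (any(n_a < 0) || any(n_b < 0))
    stop("densities must be nonnegative", call. = FALSE)
  stopifnot(eps > 0)
  pmax(n_b, eps) / pmax(n_a, eps)
}

check_ratio <- function(K) {
  if (any(!is.finite(K)) || any(K <= 0))
    stop("ratio K must be finite and > 0", call. = FALSE)
  K
}

#' Hamiltonian coefficient functions
#'
#' The density-dependent coefficients of the model, as functions of the
#' local resource/human ratio `K`:
#' \deqn{\omega^a(K) = \sigma \left[e^{-(K - 1/\tau)^2} K\right]^{1/2},
#'   \quad
#'   \omega^b(K) = \sigma \left[e^{-(K/\tau)^2} K^{-1}\right]^{1/2},}
#' \deqn{\lambda(K) = \omega^a(K) + \omega^b(K) + \mu, \quad
#'   \gamma(K_\alpha, K_\beta) = \omega^b(K_\alpha) + \omega^b(K_\beta).}
#' The square root applies to the whole bracketed product.
#' `omega_a` grows with `K` (abundant resources let the human density hold
#' its ground), `omega_b` decays with `K` (resource inertia is lost when
#' resources dominate), `lambda_coeff` sets the predator-prey exchange
#' strength, and `gamma_coeff` sets the migration strength across a
#' neighbour pair, large when either cell is resource-starved.
#'
#' @param K,K_alpha,K_beta Positive resource/human ratio(s); vectorized.
#' @param params An [model_params()] object.
#' @return Nonnegative numeric vector of coefficient values.
#' @examples
#' p <- model_params()
#' omega_a(1, p)      # ~2.229
#' omega_b(1, p)      # ~0.211
#' lambda_coeff(1, p) # omega_a + omega_b + mu
#' @export
omega_a <- function(K, params) {
  check_ratio(K)
  params$sigma * sqrt(exp(-(K - 1 / params$tau)^2) * K)
}

#' @rdname omega_a
#' @export
omega_b <- function(K, params) {
  check_ratio(K)
  params$sigma * sqrt(exp(-(K / params$tau)^2) / K)
}

#' @rdname omega_a
#' @export
lambda_coeff <- function(K, params) {
  omega_a(K, params) + omega_b(K, params) + params$mu
}

#' @rdname omega_a
#' @export
gamma_coeff <- function(K_alpha, K_beta, params) {
  omega_b(K_alpha, params) + omega_b(K_beta, params)
}

#' Per-cell coefficient field from a density field
#'
#' Evaluates `omega_a`, `omega_b` and `lambda` for every cell from its
#' instantaneous densities. Used at every integrator stage to reassemble
#' the Hamiltonian.
#'
#' @param n_a,n_b Numeric vectors of per-cell densities in `[0, 1]`.
#' @param params An [model_params()] object.
#' @return A list with numeric vectors `K`, `omega_a`, `omega_b`, `lambda`.
#' @keywords internal
#' @export
coefficient_field <- function(n_a, n_b, params) {
  K <- ratio_K(n_a, n_b, params$eps_density)
  wa <- omega_a(K, params)
  wb <- omega_b(K, params)
  list(K = K, omega_a = wa, omega_b = wb, lambda = wa + wb + params$mu)
}
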