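#' Cached Hamiltonian building blocks
#'
#' Precomputes the density-independent sparse operator structures entering
#' the Hamiltonian: per cell the number operators \eqn{N_a(\alpha)},
#' \eqn{N_b(\alpha)} and the intra-cell exchange
#' \eqn{X(\alpha) = a_\alpha^\dagger b_\alpha + b_\alpha^\dagger a_\alpha},
#' and per neighbouring pair the Hermitian migration term
#' \eqn{M(\alpha,\beta) = a_\alpha a_\beta^\dagger +
#' a_\beta a_\alpha^\dagger} (the fermionic product is taken exactly as
#' written, with its sign string). Only the scalar coefficients change
#' during a run; the structures are built once.
#'
#' @param lattice An [lattice_spec()] object.
#' @return An object of class `fp_hterms`: list with `lattice`, `pairs`
#'   (from [neighbor_pairs()]), and lists of sparse matrices `N_a`, `N_b`,
#'   `X` (per cell) and `M` (per neighbour pair).
#' @export
hamiltonian_terms <- function(lattice) {
  stopifnot(inherits(lattice, "fp_lattice"))
  M_cells <- lattice$n_cells
  N_a <- vector("list", M_cells); N_b <- vector("list", M_cells)
  X <- vector("list", M_cells)
  for (al in seq_len(M_cells)) {
    N_a[[al]] <- number_operator("a", al, lattice)
    N_b[[al]] <- number_operator("b", al, lattice)
    ad <- ladder_operator("a", al, dagger = TRUE, lattice = lattice)
    b  <- ladder_operator("b", al, dagger = FALSE, lattice = lattice)
    xab <- ad %*% b
    X[[al]] <- xab + Matrix::t(xab)
  }
  pairs <- neighbor_pairs(lattice)
  Mig <- vector("list", nrow(pairs))
  for (k in seq_len(nrow(pairs))) {
    al <- pairs[k, 1L]; be <- pairs[k, 2L]
    a_al <- ladder_operator("a", al, dagger = FALSE, lattice = lattice)
    ad_be <- ladder_operator("a", be, dagger = TRUE, lattice = lattice)
    m <- a_al %*% ad_be
    Mig[[k]] <- m + Matrix::t(m)
  }
  structure(list(lattice = lattice, pairs = pairs,
                 N_a = N_a, N_b = N_b, X = X, M = Mig),
            class = "fp_hterms")
}

#' Assemble the full Hamiltonian for a given density field
#'
#' \deqn{H = \sum_\alpha \left[\omega^a(K_\alpha) N_a(\alpha) +
#'   \omega^b(K_\alpha) N_b(\alpha) + \lambda(K_\alpha) X(\alpha)\right] +
#'   \sum_{\langle\alpha\beta\rangle} p\, \gamma(K_\alpha, K_\beta)\,
#'   M(\alpha, \beta).}
#' All coefficients are real and every cached term is Hermitian, so `H` is
#' exactly self-adjoint; it also commutes with the total number operator,
#' which is what conserves the global human + resource density.
#'
#' @param terms An [hamiltonian_terms()] cache.
#' @param n_a,n_b Per-cell density vectors (length `L^2`).
#' @param params An [model_params()] object.
#' @return A real symmetric sparse matrix of dimension `4^(L^2)`.
#' @export
assemble_hamiltonian <- function(terms, n_a, n_b, params) {
  stopifnot(inherits(terms, "fp_hterms"))
  M_cells <- terms$lattice$n_cells
  if (length(n_a) != M_cells || length(n_b) != M_cells)
    stop("density vectors must have length L^2 = ", M_cells, call. = FALSE)
  cf <- coefficient_field(n_a, n_b, params)
  H <- cf$omega_a[1L] * terms$N_a[[1L]]
  if (M_cells > 1L)
    for (al in 2:M_cells) H <- H + cf$omega_a[al] * terms$N_a[[al]]
  for (al in seq_len(M_cells)) {
    H <- H + cf$omega_b[al] * terms$N_b[[al]]
    H <- H + cf$lambda[al] * terms$X[[al]]
  }
  if (params$p > 0 && nrow(terms$pairs) > 0L) {
    for (k in seq_len(nrow(terms$pairs))) {
      al <- terms$pairs[k, 1L]; be <- terms$pairs[k, 2L]
      g <- gamma_coeff(cf$K[al], cf$K[be], params)
      H <- H + (params$p * g) * terms$M[[k]]
    }
  }
  H
}

#' Total number operator
#'
#' \eqn{\hat N = \sum_\alpha (N_a(\alpha) + N_b(\alpha))}; commutes with
#' the Hamiltonian, so the global human + resource density is conserved.
#'
#' @param lattice An [lattice_spec()] object.
#' @return Sparse diagonal matrix of dimension `4^(L^2)`.
#' @export
total_number_operator <- function(lattice) {
  stopifnot(inherits(lattice, "fp_lattice"))
  d <- numeric(lattice$dim)
  for (p in seq_len(lattice$n_modes)) d <- d + mode_bits(p, lattice)
  Matrix::Diagonal(lattice$dim, x = d)
}
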