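# Fermionic ladder and number operators on the occupation basis.
#
# Mode ordering convention: the 2 L^2 modes are ordered
# (a_1, ..., a_{L^2}, b_1, ..., b_{L^2}); a ladder operator for the mode at
# position p carries the fermionic parity string over all modes at
# positions < p. Basis states are the ordered products of creation
# operators in this same mode order applied to the vacuum, so each ladder
# matrix entry is +/-1 with the sign fixed by the string.

# parity (0/1) of the occupied modes of `x` selected by `mask`
bit_parity <- function(x, mask) {
  v <- bitwAnd(x, mask)
  p <- integer(length(v))
  while (any(v > 0L)) {
    p <- bitwXor(p, bitwAnd(v, 1L))
    v <- v %/% 2L
  }
  p
}

mode_position <- function(species, cell, lattice) {
  species <- match.arg(species, c("a", "b"))
  if (!is.numeric(cell) || length(cell) != 1L || cell < 1 ||
      cell > lattice$n_cells || cell != floor(cell))
    stop("invalid cell index ", cell, " (must be in 1..", lattice$n_cells, ")",
         call. = FALSE)
  as.integer(cell) + if (species == "b") lattice$n_cells else 0L
}

#' Fermionic ladder operator as a sparse matrix
#'
#' Builds the annihilation operator `a_alpha` (humans) or `b_alpha`
#' (resources), or its adjoint, on the full `4^(L^2)`-dimensional Fock
#' space. The operators satisfy the canonical anticommutation relations:
#' \eqn{\{a_\alpha, a_\beta^\dagger\} = \delta_{\alpha\beta} 1}, all other
#' anticommutators zero, and \eqn{a_\alpha^2 = 0}.
#'
#' @param species `"a"` (humans) or `"b"` (resources).
#' @param cell Cell index `alpha` in `1..L^2`.
#' @param dagger If `TRUE`, return the creation operator (adjoint).
#' @param lattice An [lattice_spec()] object.
#' @return A real sparse matrix (`Matrix::dgCMatrix`) of dimension
#'   `4^(L^2)`; entries are `+1`/`-1` by the fermionic sign convention.
#' @examples
#' lat <- lattice_spec(1)
#' a  <- ladder_operator("a", 1, FALSE, lat)
#' ad <- ladder_operator("a", 1, TRUE, lat)
#' Matrix::diag(a %*% ad + ad %*% a)  # all 1: {a, a^dagger} = identity
#' @export
ladder_operator <- function(species, cell, dagger = FALSE, lattice) {
  stopifnot(inherits(lattice, "fp_lattice"))
  p <- mode_position(species, cell, lattice)
  dim <- lattice$dim
  idx <- seq_len(dim) - 1L              # all basis indices
  bit <- 2L^(p - 1L)
  occ <- idx[bitwAnd(idx, bit) > 0L]    # states with the mode occupied
  tgt <- occ - bit                      # mode emptied
  string_mask <- bit - 1L               # modes at positions < p
  sgn <- 1 - 2 * bit_parity(occ, string_mask)
  # annihilation: maps |occ> -> sgn |tgt>, i.e. entry [tgt, occ]
  A <- Matrix::sparseMatrix(i = tgt + 1L, j = occ + 1L, x = sgn,
                            dims = c(dim, dim))
  if (dagger) Matrix::t(A) else A
}

#' Number operator as a sparse diagonal matrix
#'
#' The number operator \eqn{\hat n_\alpha = a_\alpha^\dagger a_\alpha} is
#' diagonal in the occupation basis; its eigenvalue on a basis state is the
#' occupation bit of that mode, interpreted as the local human (or
#' resource) density being 1.
#'
#' @inheritParams ladder_operator
#' @return A sparse diagonal matrix of dimension `4^(L^2)` with 0/1 diagonal.
#' @export
number_operator <- function(species, cell, lattice) {
  stopifnot(inherits(lattice, "fp_lattice"))
  p <- mode_position(species, cell, lattice)
  Matrix::Diagonal(lattice$dim, x = as.numeric(mode_bits(p, lattice)))
}

#' Vacuum state of the lattice Fock space
#'
#' The normalized basis vector with all occupations zero; it is annihilated
#' by every `a_alpha` and `b_alpha` and corresponds to near-absence of both
#' humans and resources everywhere.
#'
#' @param lattice An [lattice_spec()] object.
#' @return A complex vector of length `4^(L^2)` with a single unit entry.
#' @export
vacuum_state <- function(lattice) {
  stopifnot(inherits(lattice, "fp_lattice"))
  psi <- complex(lattice$dim)
  psi[1L] <- 1 + 0i
  psi
}
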