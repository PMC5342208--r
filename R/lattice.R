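#' Square lattice specification
#'
#' Defines the `L` x `L` lattice of habitat cells on which the model lives.
#' Cells are indexed `alpha = 1..L^2` in row-major order. Each cell carries
#' two fermionic modes (one for humans, one for resources), so the Fock
#' space has dimension `4^(L^2)`.
#'
#' @param L Positive integer side length of the lattice.
#' @param neighbors Adjacency rule between cells: `"von_neumann"`
#'   (4-neighbourhood, the default) or `"moore"` (8-neighbourhood).
#' @param boundary `"open"` (default) or `"periodic"`.
#'
#' @return An object of class `fp_lattice` with fields `L`, `n_cells`,
#'   `n_modes` (`= 2 L^2`), `dim` (`= 4^(L^2)`), `neighbors`, `boundary`.
#' @examples
#' lat <- lattice_spec(3)
#' lat$n_cells  # 9
#' lat$dim      # 262144
#' @export
lattice_spec <- function(L, neighbors = c("von_neumann", "moore"),
                         boundary = c("open", "periodic")) {
  if (!is.numeric(L) || length(L) != 1L || L < 1 || L != floor(L))
    stop("`L` must be a positive integer", call. = FALSE)
  L <- as.integer(L)
  n_cells <- L * L
  if (2L * n_cells > 30L)
    stop("lattice too large for a full Fock-space representation ",
         "(2*L^2 must be <= 30); use the per-cell path for large lattices",
         call. = FALSE)
  structure(
    list(L = L, n_cells = n_cells, n_modes = 2L * n_cells,
         dim = 4L^n_cells,
         neighbors = match.arg(neighbors), boundary = match.arg(boundary)),
    class = "fp_lattice")
}

#' @export
print.fp_lattice <- function(x, ...) {
  cat(sprintf("<fp_lattice> %dx%d (%d cells, %d modes, dim %d), %s adjacency, %s boundaries\n",
              x$L, x$L, x$n_cells, x$n_modes, x$dim, x$neighbors, x$boundary))
  invisible(x)
}

#' Cell index to (row, col) and back
#'
#' Row-major indexing: `alpha = (row - 1) * L + col`.
#'
#' @param alpha Cell index in `1..L^2`.
#' @param lattice An [lattice_spec()] object.
#' @return `cell_to_rc()`: integer matrix with columns `row`, `col`;
#'   `rc_to_cell()`: integer vector of cell indices.
#' @keywords internal
#' @export
cell_to_rc <- function(alpha, lattice) {
  stopifnot(all(alpha >= 1L), all(alpha <= lattice$n_cells))
  a0 <- as.integer(alpha) - 1L
  cbind(row = a0 %/% lattice$L + 1L, col = a0 %% lattice$L + 1L)
}

#' @rdname cell_to_rc
#' @param row,col Row and column indices in `1..L`.
#' @export
rc_to_cell <- function(row, col, lattice) {
  stopifnot(all(row >= 1L), all(row <= lattice$L),
            all(col >= 1L), all(col <= lattice$L))
  (as.integer(row) - 1L) * lattice$L + as.integer(col)
}

#' Neighbouring cell pairs of the lattice
#'
#' Enumerates each unordered pair of adjacent cells once. Migration acts
#' only across these pairs; the adjacency rule and boundary condition come
#' from the lattice specification.
#'
#' @param lattice An [lattice_spec()] object.
#' @return Integer matrix with columns `alpha`, `beta` (`alpha < beta`),
#'   one row per unordered neighbour pair.
#' @examples
#' nrow(neighbor_pairs(lattice_spec(3)))  # 12 edges on the open 3x3 grid
#' @export
neighbor_pairs <- function(lattice) {
  stopifnot(inherits(lattice, "fp_lattice"))
  L <- lattice$L
  if (lattice$n_cells == 1L)
    return(matrix(integer(0), ncol = 2L, dimnames = list(NULL, c("alpha", "beta"))))
  offs <- switch(lattice$neighbors,
    von_neumann = cbind(c(0L, 1L), c(1L, 0L)),
    moore       = cbind(c(0L, 1L, 1L, 1L), c(1L, 0L, 1L, -1L)))
  pairs <- NULL
  for (k in seq_len(nrow(offs))) {
    dr <- offs[k, 1L]; dc <- offs[k, 2L]
    for (r in 1:L) for (c in 1:L) {
      r2 <- r + dr; c2 <- c + dc
      if (lattice$boundary == "periodic") {
        r2 <- (r2 - 1L) %% L + 1L
        c2 <- (c2 - 1L) %% L + 1L
      } else {
        if (r2 < 1L || r2 > L || c2 < 1L || c2 > L) next
      }
      a <- rc_to_cell(r, c, lattice); b <- rc_to_cell(r2, c2, lattice)
      if (a != b) pairs <- rbind(pairs, c(min(a, b), max(a, b)))
    }
  }
  pairs <- unique(pairs)
  pairs <- pairs[order(pairs[, 1L], pairs[, 2L]), , drop = FALSE]
  colnames(pairs) <- c("alpha", "beta")
  pairs
}

#' Encode / decode occupation bitstrings
#'
#' The occupation basis state is the pair of bit vectors `(m_a, m_b)` giving
#' the human and resource occupation of every cell. Its linear index reads
#' the concatenated bitstring `(m_a, m_b)` as an integer with the human
#' mode of cell 1 as the least-significant bit, giving a bijection onto
#' `0 .. 4^(L^2) - 1`.
#'
#' @param m_a,m_b Integer vectors of length `L^2` with entries in `{0, 1}`:
#'   human and resource occupations per cell.
#' @param lattice An [lattice_spec()] object.
#' @return `encode_occupation()`: a single integer index in
#'   `[0, 4^(L^2))`; `decode_occupation()`: a list with fields `m_a`, `m_b`.
#' @examples
#' lat <- lattice_spec(2)
#' idx <- encode_occupation(c(1, 0, 0, 0), c(0, 0, 0, 1), lat)
#' decode_occupation(idx, lat)
#' @export
encode_occupation <- function(m_a, m_b, lattice) {
  stopifnot(inherits(lattice, "fp_lattice"))
  M <- lattice$n_cells
  if (length(m_a) != M || length(m_b) != M)
    stop("occupation vectors must have length L^2 = ", M, call. = FALSE)
  bits <- c(m_a, m_b)
  if (!all(bits %in% c(0, 1)))
    stop("occupation entries must be 0 or 1", call. = FALSE)
  sum(as.integer(bits) * 2L^(seq_along(bits) - 1L))
}

#' @rdname encode_occupation
#' @param index Linear basis index in `[0, 4^(L^2))`.
#' @export
decode_occupation <- function(index, lattice) {
  stopifnot(inherits(lattice, "fp_lattice"))
  if (index < 0 || index >= lattice$dim || index != floor(index))
    stop("index must be an integer in [0, ", lattice$dim, ")", call. = FALSE)
  M <- lattice$n_cells
  bits <- as.integer(intToBits(as.integer(index)))[seq_len(2L * M)]
  list(m_a = bits[seq_len(M)], m_b = bits[M + seq_len(M)])
}

# Occupation bit of mode `pos` (1-based over the 2 L^2 modes, a-block then
# b-block) for every basis index 0..dim-1, as a 0/1 integer vector.
mode_bits <- function(pos, lattice) {
  idx <- seq_len(lattice$dim) - 1L
  bitwAnd(idx %/% (2L^(pos - 1L)), 1L)
}
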