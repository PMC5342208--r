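# shared helpers for the fockpop test suite

# random unit-norm complex state on a lattice Fock space
random_state <- function(lattice, seed = 1) {
  set.seed(seed)
  v <- complex(real = rnorm(lattice$dim), imaginary = rnorm(lattice$dim))
  v / sqrt(sum(Mod(v)^2))
}

# all ladder operators of a lattice, as a named list
all_ladders <- function(lattice, dagger = FALSE) {
  ops <- list()
  for (sp in c("a", "b"))
    for (al in seq_len(lattice$n_cells))
      ops[[paste0(sp, al)]] <-
        ladder_operator(sp, al, dagger = dagger, lattice = lattice)
  ops
}

max_abs <- function(m) max(abs(m))

# cache of expensive shared runs (computed once per test session)
.run_cache <- new.env(parent = emptyenv())
cached <- function(key, expr) {
  if (!exists(key, envir = .run_cache)) assign(key, expr, envir = .run_cache)
  get(key, envir = .run_cache)
}
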