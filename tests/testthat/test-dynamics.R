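test_that("densities read off a state follow the number-operator rule", {
  lat <- lattice_spec(1)
  # equal superposition of vacuum and doubly-occupied state
  psi <- complex(4)
  psi[encode_occupation(0, 0, lat) + 1L] <- 1 / sqrt(2)
  psi[encode_occupation(1, 1, lat) + 1L] <- 1 / sqrt(2)
  d <- densities_from_state(psi, lat)
  expect_equal(d$n_a, 0.5)
  expect_equal(d$n_b, 0.5)
  # basis state: eigenvalue is the occupation bit
  lat2 <- lattice_spec(2)
  psi2 <- complex(lat2$dim)
  psi2[encode_occupation(c(1, 0, 0, 1), c(0, 1, 0, 0), lat2) + 1L] <- 1
  d2 <- densities_from_state(psi2, lat2)
  expect_equal(d2$n_a, c(1, 0, 0, 1))
  expect_equal(d2$n_b, c(0, 1, 0, 0))
  expect_error(densities_from_state(complex(8), lat2), "length")
})

test_that("compiled kernel agrees with the sparse-matrix reference integrator", {
  lat <- lattice_spec(2)
  psi0 <- initial_state(init_spec(seed = 7), lat)
  tk <- cached("kernel_L2", evolve(psi0, model_params(), lat, horizon = 0.5,
                                   dt = 1e-3, record_every = 50))
  tr <- evolve(psi0, model_params(), lat, horizon = 0.5, dt = 1e-3,
               record_every = 50, method = "reference")
  expect_lt(max(abs(tk$n_a - tr$n_a)), 1e-12)
  expect_lt(max(abs(tk$n_b - tr$n_b)), 1e-12)
})

test_that("norm and global human+resource density are conserved", {
  lat <- lattice_spec(2)
  psi0 <- initial_state(init_spec(seed = 7), lat)
  tr <- cached("kernel_L2_long", evolve(psi0, model_params(), lat,
                                        horizon = 5, dt = 1e-3,
                                        record_every = 20))
  chk <- conservation_check(tr, tol = 1e-6)
  expect_lt(chk$max_conservation_dev, 1e-6)
  expect_lt(chk$max_norm_dev, 1e-6)
  expect_true(chk$pass)
  # densities never leave [0, 1]
  expect_true(all(tr$n_a >= 0 & tr$n_a <= 1))
  expect_true(all(tr$n_b >= 0 & tr$n_b <= 1))
  # global series equals the sum of per-cell series
  expect_equal(tr$global_a, rowSums(tr$n_a))
  # a tampered trajectory is flagged
  bad <- tr
  bad$global_a[10] <- bad$global_a[10] + 1e-3
  expect_false(conservation_check(bad, tol = 1e-6)$pass)
})

test_that("per-cell fast path matches the full Fock-space evolution when p = 0", {
  lat <- lattice_spec(2)
  init <- init_spec(seed = 11)
  p0 <- model_params(p = 0)
  psi0 <- initial_state(init, lat)
  pc0 <- initial_state_percell(init, 4)
  tf <- evolve(psi0, p0, lat, horizon = 2, dt = 2.5e-4, record_every = 40)
  tp <- evolve_percell(pc0, p0, horizon = 2, dt = 2.5e-4, record_every = 40)
  expect_lt(max(abs(tf$n_a - tp$n_a)), 1e-8)
  expect_lt(max(abs(tf$n_b - tp$n_b)), 1e-8)
  # per-cell conservation: n_a + n_b constant in every decoupled cell
  tot <- tp$n_a + tp$n_b
  expect_lt(max(abs(sweep(tot, 2, tot[1, ]))), 1e-6)
  expect_error(evolve_percell(pc0, model_params(p = 1), horizon = 1),
               "p = 0")
})

test_that("frozen-coefficient one-cell run matches the Rabi closed form", {
  lat <- lattice_spec(1)
  psi0 <- complex(4)
  psi0[encode_occupation(1, 0, lat) + 1L] <- 1   # start at phi_{1,0}
  lam <- 2.0
  ov <- list(omega_a = 1.3, omega_b = 1.3, lambda = lam)  # zero detuning
  tr <- evolve(psi0, model_params(), lat, horizon = 3, dt = 5e-4,
               record_every = 10, method = "reference", coeff_override = ov)
  expect_lt(max(abs(tr$n_a[, 1] - cos(lam * tr$time)^2)), 1e-6)
  expect_lt(max(abs(tr$n_b[, 1] - sin(lam * tr$time)^2)), 1e-6)
})

test_that("halving dt shrinks the error at the integrator's order", {
  lat <- lattice_spec(2)
  psi0 <- initial_state(init_spec(seed = 3), lat)
  pm <- model_params()
  ref <- evolve(psi0, pm, lat, horizon = 0.4, dt = 5e-5, record_every = 2000)
  err <- sapply(c(8e-4, 4e-4, 2e-4), function(h) {
    tr <- evolve(psi0, pm, lat, horizon = 0.4, dt = h,
                 record_every = round(0.1 / h))
    max(abs(tr$n_a[nrow(tr$n_a), ] - ref$n_a[nrow(ref$n_a), ]))
  })
  # RK4: each halving should divide the error by about 16
  expect_gt(err[1] / err[2], 10)
  expect_gt(err[2] / err[3], 10)
})

test_that("trajectory containers are consistent and exportable", {
  lat <- lattice_spec(2)
  psi0 <- initial_state(init_spec(seed = 7), lat)
  tr <- cached("kernel_L2", evolve(psi0, model_params(), lat, horizon = 0.5,
                                   dt = 1e-3, record_every = 50))
  df <- as.data.frame(tr)
  expect_named(df, c("time", "cell_id", "species", "density"))
  # 4 cells + 1 global series per species
  expect_equal(length(unique(df$cell_id)), 5L)
  glob <- df[df$cell_id == "global" & df$species == "a", ]
  percell <- df[df$cell_id != "global" & df$species == "a", ]
  sums <- tapply(percell$density, percell$time, sum)
  expect_equal(as.numeric(sums[as.character(glob$time)]), glob$density)
})
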