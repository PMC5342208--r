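test_that("initialization hits the global carrying capacity exactly", {
  init <- init_spec(K_total = 0.5, jitter = 0.10, seed = 42)
  d <- initial_densities(init, 9)
  expect_equal(sum(d$n_a), 0.5)                       # global condition
  target <- 0.5 / 9
  expect_true(all(d$n_a >= 0.9 * target))             # within the 10% band
  expect_true(all(d$n_a <= 1.1 * target))
  expect_equal(d$n_a + d$n_b, rep(2 * target, 9))     # complementary resources
  # same seed reproduces the draw bit for bit; different seed does not
  d2 <- initial_densities(init, 9)
  expect_identical(d$n_a, d2$n_a)
  d3 <- initial_densities(init_spec(seed = 43), 9)
  expect_false(identical(d$n_a, d3$n_a))
})

test_that("initialization is rejected when infeasible", {
  expect_error(initial_densities(init_spec(K_total = 1, jitter = 0.1), 1),
               "infeasible")
})

test_that("full-space initial state realizes the drawn densities", {
  lat <- lattice_spec(2)
  init <- init_spec(seed = 5)
  psi0 <- initial_state(init, lat)
  expect_equal(sqrt(sum(Mod(psi0)^2)), 1)
  d_target <- initial_densities(init, 4)
  d_state <- densities_from_state(psi0, lat)
  expect_equal(d_state$n_a, d_target$n_a, tolerance = 1e-12)
  expect_equal(d_state$n_b, d_target$n_b, tolerance = 1e-12)
  # per-cell variant realizes the same densities
  pc <- initial_state_percell(init, 4)
  expect_equal(Mod(pc[2, ])^2 + Mod(pc[4, ])^2, d_target$n_a)
  expect_equal(Mod(pc[3, ])^2 + Mod(pc[4, ])^2, d_target$n_b)
})

test_that("run_scenario wires scenarios, labels and fast path correctly", {
  init <- init_spec(seed = 2)
  tr <- run_scenario("no_migration", model_params(), 9, init,
                     horizon = 1, dt = 1e-3, record_every = 10)
  expect_s3_class(tr, "fp_trajectory")
  expect_equal(tr$scenario, "no_migration")
  expect_equal(tr$seed, 2L)
  expect_equal(tr$method, "percell")
  expect_equal(tr$params$p, 0)              # forced even though default p = 1
  expect_equal(ncol(tr$n_a), 9L)
  # single-cell system: global equals the only local series
  tr1 <- run_scenario("no_migration", model_params(), 1, init,
                      horizon = 0.5, dt = 1e-3, record_every = 10)
  expect_equal(tr1$global_a, tr1$n_a[, 1])
  # migration needs a genuine lattice and p > 0
  expect_error(run_scenario("migration", model_params(), 9, init, horizon = 1),
               "lattice")
  expect_error(run_scenario("migration", model_params(p = 0), lattice_spec(2),
                            init, horizon = 1), "p > 0")
})

test_that("same seed gives a bit-identical trajectory", {
  init <- init_spec(seed = 9)
  t1 <- run_scenario("no_migration", model_params(), 9, init,
                     horizon = 1, dt = 1e-3, record_every = 10)
  t2 <- run_scenario("no_migration", model_params(), 9, init,
                     horizon = 1, dt = 1e-3, record_every = 10)
  expect_identical(t1$n_a, t2$n_a)
  expect_identical(t1$n_b, t2$n_b)
})

test_that("migration coupling switches on large synchronized oscillations", {
  # 2x2 torus: small enough for fast full-Fock sweeps over p
  sw <- parameter_sweep("p", values = c(0, 1), seeds = 1:2,
                        params = model_params(),
                        lattice = lattice_spec(2, boundary = "periodic"),
                        init = init_spec(), horizon = 15, dt = 1e-3,
                        record_every = 20, norm_tol = 1e-5)
  s <- sw$summary
  for (seed in 1:2) {
    amp0 <- s$amplitude[s$value == 0 & s$seed == seed]
    amp1 <- s$amplitude[s$value == 1 & s$seed == seed]
    expect_lt(amp0, 0.25)          # near-flat without migration
    expect_gt(amp1 / amp0, 3)      # migration amplifies the global swing
    # without migration the global density never swings as far as the
    # migration run does
    expect_lt(amp0, min(s$amplitude[s$value == 1]))
  }
})

test_that("parameter sweep returns one run and one summary row per cell", {
  sw <- parameter_sweep("mu", values = c(0.1, 0.25), seeds = c(1, 2),
                        params = model_params(p = 0), lattice = 9,
                        horizon = 2, dt = 1e-3, record_every = 10)
  expect_length(sw$runs, 4L)
  expect_equal(nrow(sw$summary), 4L)
  expect_setequal(sw$summary$value, c(0.1, 0.25))
  expect_true(all(c("min_ratio", "max_ratio", "std_ratio",
                    "n_major_peaks") %in% names(sw$summary)))
  # single value, single seed = single run
  sw1 <- parameter_sweep("sigma", values = 12.5, seeds = 1,
                         params = model_params(p = 0), lattice = 4,
                         horizon = 1, dt = 1e-3, record_every = 10)
  expect_length(sw1$runs, 1L)
})
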