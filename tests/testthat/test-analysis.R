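make_series <- function(time, value) data.frame(time = time, value = value)

test_that("oscillation interval recovers the extremes relative to K", {
  t <- seq(0, 10, by = 0.01)
  s <- make_series(t, 0.5 * (1 + 0.2 * sin(2 * pi * t)))
  osc <- oscillation_interval(s, K = 0.5, transient = 0)
  expect_equal(osc$min_ratio, 0.8, tolerance = 1e-3)
  expect_equal(osc$max_ratio, 1.2, tolerance = 1e-3)
  # constant series at K
  osc0 <- oscillation_interval(make_series(t, rep(0.5, length(t))), K = 0.5)
  expect_equal(osc0$min_ratio, 1)
  expect_equal(osc0$max_ratio, 1)
  expect_equal(osc0$std_ratio, 0)
  # invariant under time reparameterization
  osc2 <- oscillation_interval(make_series(t^2, s$value), K = 0.5,
                               transient = 0)
  expect_equal(osc2$min_ratio, osc$min_ratio)
  expect_equal(osc2$max_ratio, osc$max_ratio)
  expect_error(oscillation_interval(s, window = c(99, 100), K = 0.5),
               "empty")
  expect_error(oscillation_interval(s), "K")   # raw series needs K
})

test_that("major extreme counting matches the analytic sinusoid", {
  t <- seq(0, 3, by = 1e-3)                    # three full periods
  clean <- make_series(t, sin(2 * pi * t))
  ext <- count_extremes(clean, closeness = 0.1, K = 1, transient = 0)
  expect_equal(ext[["n_major_peaks"]], 3L)
  expect_equal(ext[["n_major_valleys"]], 3L)
  # small high-frequency ripple must not add major extremes
  ripple <- make_series(t, sin(2 * pi * t) + 0.05 * sin(40 * pi * t))
  extr <- count_extremes(ripple, closeness = 0.1, K = 1, transient = 0)
  expect_equal(extr[["n_major_peaks"]], 3L)
  expect_equal(extr[["n_major_valleys"]], 3L)
  # constant series has none
  ext0 <- count_extremes(make_series(t, rep(2, length(t))), K = 1,
                         transient = 0)
  expect_equal(unname(ext0), c(0L, 0L))
  # invariance under shift and scale
  shifted <- make_series(t, 5 + 3 * sin(2 * pi * t))
  expect_equal(count_extremes(shifted, closeness = 0.1, K = 1, transient = 0),
               ext)
})

test_that("smoothing metric orders no-migration runs by cell count", {
  mk <- function(n_cells, sdv, seed) {
    set.seed(seed)
    t <- seq(0, 10, by = 0.01)
    g <- 0.5 + stats::filter(rnorm(length(t), sd = sdv), rep(1, 5))
    g[is.na(g)] <- 0.5
    tr <- structure(list(
      time = t, n_a = matrix(g / n_cells, length(t), n_cells),
      n_b = matrix(0.5 / n_cells, length(t), n_cells),
      global_a = as.numeric(g), global_b = rep(0.5, length(t)),
      norm = rep(1, length(t)), params = model_params(p = 0),
      lattice = list(n_cells = n_cells), dt = 0.01, method = "percell",
      scenario = "no_migration", seed = seed, status = "ok"),
      class = "fp_trajectory")
    tr
  }
  trajs <- list(mk(1000, 0.001, 1), mk(9, 0.01, 2), mk(100, 0.005, 3))
  tab <- smoothing_metric(trajs)
  expect_equal(tab$n_cells, c(9L, 100L, 1000L))       # sorted
  expect_true(all(diff(tab$std_ratio) < 0))           # decreasing
  # identical duplicated runs give equal std
  tab2 <- smoothing_metric(list(mk(9, 0.01, 5), mk(9, 0.01, 5)))
  expect_equal(tab2$std_ratio[1], tab2$std_ratio[2])
  # mixed scenarios rejected
  bad <- mk(9, 0.01, 1); bad$scenario <- "migration"; bad$params$p <- 1
  expect_error(smoothing_metric(list(bad)), "no-migration")
})

test_that("reference comparison reproduces the interval arithmetic", {
  ref <- make_reference_fixture(K_ref = 0.185, min_ratio = 0.70,
                                max_ratio = 1.57, n_periods = 5,
                                n_points = 800, seed = 4)
  # analyzer recovers the generator's interval exactly
  osc <- oscillation_interval(ref, K = 0.185, transient = 0)
  expect_equal(osc$min_ratio, 0.70, tolerance = 1e-9)
  expect_equal(osc$max_ratio, 1.57, tolerance = 1e-9)
  # a synthetic "model" trajectory with interval (0.66, 1.50): differences
  # must equal |0.66 - 0.70| and |1.50 - 1.57|
  t <- seq(0, 10, by = 0.005)
  g <- 0.5 * (1.08 + 0.42 * sin(2 * pi * t))   # ratios 0.66 .. 1.50
  tr <- structure(list(
    time = t, n_a = matrix(g, length(t), 1), n_b = matrix(0.5, length(t), 1),
    global_a = g, global_b = rep(0.5, length(t)), norm = rep(1, length(t)),
    params = model_params(), lattice = list(n_cells = 1), dt = 0.005,
    method = "kernel", scenario = "migration", seed = 1, status = "ok"),
    class = "fp_trajectory")
  cmp <- compare_reference(tr, ref, K_ref = 0.185, transient = 0)
  expect_equal(unname(cmp$interval_diff["lower"]), 0.04, tolerance = 1e-3)
  expect_equal(unname(cmp$interval_diff["upper"]), 0.07, tolerance = 1e-3)
  # trajectory compared with itself: zero differences
  self_ref <- data.frame(time = t, value = g)
  cmp2 <- compare_reference(tr, self_ref, K_ref = 0.5, transient = 0)
  # model side drops a transient window; align by using the same series
  expect_lt(cmp2$interval_diff["upper"], 0.01)
  expect_error(compare_reference(tr, data.frame(time = 1, value = 1),
                                 K_ref = 1), "at least 2")
})
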