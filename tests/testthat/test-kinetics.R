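test_that("survival curves count remaining tethers on the frame grid", {
  d <- data.frame(time_s = 1:4, censored = 0L)
  sc <- build_survival_curve(d, frame_interval = 1, t_end = 4)
  expect_equal(sc$times, 0:4)
  expect_equal(sc$fraction_remaining, c(1, 0.75, 0.5, 0.25, 0))

  # all censored: constant 1
  dc <- data.frame(time_s = rep(100, 5), censored = 1L)
  scc <- build_survival_curve(dc, frame_interval = 10, t_end = 100)
  expect_true(all(scc$fraction_remaining == 1))
  expect_equal(scc$n_censored, 5)

  # remaining counts are integers at every grid time
  m <- tether_population_model(87, off_rate = 0.02, duration = 600, seed = 7)
  ds <- sample_dissociation_times(m)$dataset
  sc2 <- build_survival_curve(ds, frame_interval = 5)
  expect_equal(sc2$fraction_remaining * sc2$n_total,
               round(sc2$fraction_remaining * sc2$n_total))
  expect_true(all(diff(sc2$fraction_remaining) <= 0))
  expect_equal(sc2$fraction_remaining[1], 1)
  expect_gte(min(sc2$fraction_remaining), sc2$n_censored / sc2$n_total)

  expect_error(build_survival_curve(data.frame(time_s = numeric(0),
                                               censored = integer(0))),
               "at least one")
})

test_that("empirical survival stays inside the DKW band around e^(-kt)", {
  k <- 0.05
  for (seed in 1:5) {
    m <- tether_population_model(16, off_rate = k, stuck_fraction = 0,
                                 slow_fraction = 0, duration = 1e6,
                                 seed = seed)
    d <- sample_dissociation_times(m)$dataset
    sc <- build_survival_curve(d, frame_interval = 2,
                               t_end = max(d$time_s))
    eps <- sqrt(log(2 / 0.05) / (2 * 16))  # DKW 95% band
    expect_true(all(abs(sc$fraction_remaining - exp(-k * sc$times)) <=
                    eps + 1e-12))
  }
})

test_that("noiseless exponential curves are fit exactly", {
  t <- seq(0, 600, by = 5)
  mk_curve <- function(y) structure(
    list(times = t, fraction_remaining = y, n_total = 1000L,
         n_censored = 0L, frame_interval = 5), class = "survival_curve")
  f1 <- fit_single_exponential(mk_curve(exp(-0.01 * t)))
  expect_true(f1$converged)
  expect_equal(f1$k, 0.01, tolerance = 1e-6)
  expect_equal(f1$A, 1, tolerance = 1e-6)
  expect_lt(f1$y0, 1e-6)

  f2 <- fit_single_exponential(mk_curve(0.1 + 0.9 * exp(-0.05 * t)))
  expect_equal(f2$k, 0.05, tolerance = 1e-6)
  expect_equal(f2$A, 0.9, tolerance = 1e-6)
  expect_equal(f2$y0, 0.1, tolerance = 1e-6)
  expect_gt(f2$r_squared, 1 - 1e-10)
})

test_that("survival-curve fit agrees with the censored exponential MLE", {
  m <- tether_population_model(1000, off_rate = 0.02, stuck_fraction = 0,
                               slow_fraction = 0, duration = 250, seed = 31)
  d <- sample_dissociation_times(m)$dataset
  f <- fit_single_exponential(build_survival_curve(d, frame_interval = 1))
  k_hat <- censored_mle_rate(d)
  expect_lt(abs(f$k - k_hat) / k_hat, 0.05)
})

test_that("rescaling all times rescales the fitted rate inversely", {
  m <- tether_population_model(200, off_rate = 0.02, duration = 1200,
                               seed = 77)
  d <- sample_dissociation_times(m)$dataset
  f1 <- fit_single_exponential(build_survival_curve(d, frame_interval = 5))
  for (c_scale in c(10, 0.25)) {
    d2 <- d
    d2$time_s <- d$time_s * c_scale
    attr(d2, "duration") <- attr(d, "duration") * c_scale
    f2 <- fit_single_exponential(
      build_survival_curve(d2, frame_interval = 5 * c_scale))
    expect_equal(f2$k * c_scale, f1$k, tolerance = 1e-8)
    expect_equal(f2$A, f1$A, tolerance = 1e-8)
    expect_equal(f2$y0, f1$y0, tolerance = 1e-8)
  }
})

test_that("rate recovery improves with sample size across the k grid", {
  rel_err <- function(k, n, stuck, seed) {
    m <- tether_population_model(n, off_rate = k, stuck_fraction = stuck,
                                 slow_fraction = 0, duration = 6 / k,
                                 seed = seed)
    d <- sample_dissociation_times(m)$dataset
    f <- fit_single_exponential(
      build_survival_curve(d, frame_interval = 6 / k / 300))
    abs(f$k - k) / k
  }
  grid <- expand.grid(k = c(1e-3, 1e-2, 1e-1), n = c(50, 200, 1000),
                      stuck = c(0, 0.05))
  grid$err <- mapply(rel_err, grid$k, grid$n, grid$stuck,
                     seed = 100 + seq_len(nrow(grid)))
  med <- tapply(grid$err, grid$n, median)
  expect_lt(med[["200"]], 0.10)
  expect_lt(med[["1000"]], med[["50"]])
})

test_that("histogram bin widths track the data span in whole frames", {
  mk <- function(times) {
    d <- data.frame(time_s = times,
                    censored = rep(0L, length(times)))
    class(d) <- c("dissociation_dataset", "data.frame")
    d
  }
  h1 <- histogram_dissociation(mk(c(seq(1, 99), 100)), target_bins = 20,
                               frame_interval = 1)
  expect_equal(h1$bin_width, 5)
  expect_equal(length(h1$counts), 20)
  h2 <- histogram_dissociation(mk(c(seq(10, 990, 10), 1000)),
                               target_bins = 20, frame_interval = 1)
  expect_equal(h2$bin_width, 50)
  # degenerate span: width floors at one saved frame
  h3 <- histogram_dissociation(mk(c(1, 3, 7)), target_bins = 20,
                               frame_interval = 1)
  expect_equal(h3$bin_width, 1)
  expect_error(histogram_dissociation(
    mk(numeric(0))), "no dissociation events")
})

test_that("replicate off-rates aggregate to mean and standard deviation", {
  mk_fit <- function(k) structure(
    list(k = k, A = 1, y0 = 0, r_squared = 0.999, n = 100L,
         converged = TRUE), class = "exponential_fit")
  est <- aggregate_replicates(lapply(c(0.010, 0.012, 0.011), mk_fit),
                              construct = "A|C", force = 15)
  expect_equal(est$k_mean, 0.011)
  expect_equal(est$k_sd, 0.001)
  expect_false(est$low_replicates)

  expect_warning(single <- aggregate_replicates(list(mk_fit(0.02))),
                 "fewer than 3")
  expect_equal(single$k_mean, 0.02)
  expect_equal(single$k_sd, 0)
  expect_true(single$low_replicates)

  bad <- structure(list(k = NA, converged = FALSE, n = 0),
                   class = "exponential_fit")
  expect_error(aggregate_replicates(list(bad)), "no converged")
})

test_that("replicate means concentrate around the true off-rate", {
  k_true <- 0.02
  ds <- lapply(1:3, function(i) {
    m <- tether_population_model(500, off_rate = k_true, stuck_fraction = 0,
                                 slow_fraction = 0, duration = 600,
                                 seed = 50 + i)
    sample_dissociation_times(m)$dataset
  })
  est <- fit_replicates(ds, frame_interval = 5, construct = "sim",
                        force = 15)$estimate
  # sampling sd of one replicate's k is about k / sqrt(n)
  expect_lt(abs(est$k_mean - k_true), 3 * (k_true / sqrt(500)) / sqrt(3))
  expect_equal(est$n_tethers_total, 1500)
})
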