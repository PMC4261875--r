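# Build a frequency_matrix by hand for CDF arithmetic tests.
hand_matrix <- function(counts_ge, n_reps, times, f_obs) {
  freq <- vapply(counts_ge, function(k)
    c(rep(f_obs, k), rep(0, n_reps - k)), numeric(n_reps))
  structure(list(freq = freq, times = times, model_id = "hand", rate = 1,
                 grid = simulation_grid(t_min = times[1],
                                        t_max = times[length(times)],
                                        step = times[2] - times[1],
                                        n_reps = n_reps)),
            class = "frequency_matrix")
}

test_that("simulation grid validates its geometry", {
  g <- simulation_grid()
  expect_equal(g$times, seq(5, 200, by = 5))
  expect_equal(g$n_reps, 1000L)
  expect_error(simulation_grid(t_min = 0), "t_min")
  expect_error(simulation_grid(t_min = 5, t_max = 17, step = 5), "divisible")
  expect_error(simulation_grid(n_reps = 0), "n_reps")
})

test_that("exceedance CDF is the direct count, monotone-enforced", {
  fm <- hand_matrix(c(100, 400, 900), 1000, c(5, 10, 15), f_obs = 0.02)
  cdf <- build_age_cdf(fm, 0.02)
  expect_equal(cdf$q_raw, c(0.10, 0.40, 0.90))
  expect_equal(cdf$q, c(0.10, 0.40, 0.90))

  # non-monotone raw counts are smoothed by the running maximum
  fm2 <- hand_matrix(c(400, 100, 995), 1000, c(5, 10, 15), f_obs = 0.02)
  cdf2 <- build_age_cdf(fm2, 0.02)
  expect_equal(cdf2$q, c(0.40, 0.40, 0.995))
  expect_true(all(diff(cdf2$q) >= 0))
})

test_that("f_obs = 0 gives a unit CDF with median at t_min", {
  s <- make_coding_sequence(100, seed = 1)
  g <- simulation_grid(t_min = 5, t_max = 20, step = 5, n_reps = 50, seed = 1)
  fm <- simulate_stop_frequencies(s, neutral_model(2.2e-9), g)
  cdf <- build_age_cdf(fm, 0)
  expect_true(all(cdf$q == 1))
  expect_equal(summarize_age(cdf)$median, 5)
})

test_that("unattainable target frequencies are refused, not truncated", {
  s <- make_coding_sequence(100, seed = 2)
  g <- simulation_grid(t_min = 5, t_max = 20, step = 5, n_reps = 50, seed = 1)
  fm <- simulate_stop_frequencies(s, neutral_model(2.2e-9), g)
  cdf <- build_age_cdf(fm, 1)
  expect_false(cdf$reached)
  expect_error(summarize_age(cdf), "not attained")
})

test_that("age summaries integrate the discrete mass correctly", {
  # degenerate step CDF jumping 0 -> 1 at t = 50
  fm <- hand_matrix(c(0, 0, 0, 0, 0, 0, 0, 0, 0, 1000), 1000,
                    seq(5, 50, by = 5), f_obs = 0.05)
  sm <- summarize_age(build_age_cdf(fm, 0.05))
  expect_equal(sm$mean, 50)
  expect_equal(sm$median, 50)
  expect_equal(sm$mode, c(45, 50))
  expect_equal(sm$ci95, c(50, 50))

  # hand integration: q = (0.10, 0.40, 0.90, 1.0) at t = (5, 10, 15, 20)
  fm2 <- hand_matrix(c(100, 400, 900, 1000), 1000, c(5, 10, 15, 20),
                     f_obs = 0.05)
  sm2 <- summarize_age(build_age_cdf(fm2, 0.05))
  expect_equal(sm2$mean, 5 * 0.10 + 10 * 0.30 + 15 * 0.50 + 20 * 0.10)
  expect_equal(sm2$median, 15)

  # renormalization conserves mass
  fm3 <- hand_matrix(c(200, 600, 992), 1000, c(5, 10, 15), f_obs = 0.05)
  cdf3 <- build_age_cdf(fm3, 0.05)
  qn <- cdf3$q / cdf3$q[3]
  expect_equal(sum(diff(c(0, qn))), 1)
  expect_true(cdf3$reached)
})

test_that("simulation is reproducible and content-seeded", {
  m <- neutral_model(2.2e-9)
  g <- simulation_grid(t_min = 10, t_max = 40, step = 10, n_reps = 100,
                       seed = 5)
  s <- make_coding_sequence(200, seed = 3, id = "a")
  fm1 <- simulate_stop_frequencies(s, m, g)
  fm2 <- simulate_stop_frequencies(s, m, g)
  expect_identical(fm1$freq, fm2$freq)

  # identical bases under a different id give identical summaries
  s2 <- s
  s2$id <- "b"
  fm3 <- simulate_stop_frequencies(s2, m, g)
  expect_identical(fm1$freq, fm3$freq)

  # a different master seed changes the draw
  g2 <- simulation_grid(t_min = 10, t_max = 40, step = 10, n_reps = 100,
                        seed = 6)
  expect_false(identical(simulate_stop_frequencies(s, m, g2)$freq, fm1$freq))
})

test_that("larger observed frequencies never yield younger medians", {
  m <- neutral_model(2.2e-9)
  g <- simulation_grid(t_min = 5, t_max = 150, step = 5, n_reps = 300,
                       seed = 8)
  s <- make_coding_sequence(400, seed = 9)
  fm <- simulate_stop_frequencies(s, m, g)
  f_grid <- c(0.002, 0.005, 0.008, 0.012)
  meds <- vapply(f_grid, function(f) {
    cdf <- build_age_cdf(fm, f)
    if (!cdf$reached) return(NA_real_)
    summarize_age(cdf)$median
  }, numeric(1))
  meds <- meds[!is.na(meds)]
  expect_true(all(diff(meds) >= 0))
})

test_that("multi-model dating reports per-model and pooled summaries", {
  m <- neutral_model(2.2e-9)
  g <- simulation_grid(t_min = 10, t_max = 120, step = 10, n_reps = 200,
                       seed = 12)
  s1 <- make_coding_sequence(300, seed = 13)
  rep1 <- date_erv(s1, m, g, f_obs = 0.01)
  expect_length(rep1$per_model, 1L)
  # single model: pooled range collapses
  expect_equal(rep1$mean_range[1], rep1$mean_range[2])
  expect_equal(rep1$pooled$mean, rep1$per_model[[1]]$mean)

  # two identical model sequences, same grid seed: identical summaries
  s2 <- s1
  s2$id <- "copy"
  rep2 <- date_erv(list(s1, s2), m, g, f_obs = 0.01)
  expect_equal(rep2$per_model[[1]]$mean, rep2$per_model[[2]]$mean)
  expect_equal(rep2$mean_range[1], rep2$mean_range[2])
})
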