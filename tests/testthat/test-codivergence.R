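test_that("congruent trees yield one pair per non-root branch with host durations", {
  # 4-tip ladder, ultrametric host with known node ages
  ht <- ape::read.tree(text = "(((a:10,b:10):10,c:20):10,d:30);")
  vt <- ape::read.tree(text = "(((A:0.1,B:0.1):0.1,C:0.2):0.1,D:0.3);")
  as <- tip_association(c("A", "B", "C", "D"), c("a", "b", "c", "d"))
  ages <- node_ages_from_tree(ht)
  r <- reconcile(vt, ht, as)
  pairs <- extract_branch_pairs(r, vt, ht, ages)
  expect_equal(nrow(pairs), 6L)           # 4 terminal + 2 internal branches
  expect_setequal(
    pairs$host_duration[match(c("a", "b", "c", "d"), pairs$host_branch)],
    c(10, 10, 20, 30))
  expect_equal(pairs$host_duration[pairs$host_branch == "a+b"], 10)

  # conservation: durations along any root-to-tip path sum to the root age
  expect_equal(pairs$host_duration[pairs$host_branch == "a+b"] +
                 pairs$host_duration[pairs$host_branch == "a"] +
                 pairs$host_duration[pairs$host_branch == "a+b+c"], 30)
})

test_that("switched tips are excluded from codivergent pairs", {
  base <- make_cophylo_pair(8, n_switches = 0, seed = 51)
  r0 <- reconcile(base$vtree, base$htree, base$assoc)
  p0 <- extract_branch_pairs(r0, base$vtree, base$htree, base$ages)

  sw <- make_cophylo_pair(8, n_switches = 1, seed = 51)
  r1 <- reconcile(sw$vtree, sw$htree, sw$assoc)
  expect_lt(r1$n_cospeciations, r0$n_cospeciations)
  p1 <- extract_branch_pairs(r1, sw$vtree, sw$htree, sw$ages)
  expect_lt(nrow(p1), nrow(p0))
})

test_that("exact colinear points are fitted perfectly with nothing pruned", {
  pairs <- data.frame(host_duration = c(1, 3, 5, 7, 9),
                      virus_branch_length = 2 * c(1, 3, 5, 7, 9))
  fit <- fit_codivergence(pairs)
  expect_equal(fit$slope, 2, tolerance = 1e-12)
  expect_equal(fit$intercept, 0, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1)
  expect_equal(nrow(fit$removed), 0L)
  expect_equal(fit$n_used, 5L)
})

test_that("OLS matches the normal-equations oracle when pruning is disabled", {
  pr <- make_regression_pairs(30, slope = 0.007, intercept = 0.01,
                              noise_sd = 0.05, seed = 61)
  fit <- fit_codivergence(pr, cook_factor = Inf)
  oracle <- normal_equations_ols(pr$host_duration, pr$virus_branch_length)
  expect_equal(fit$slope, unname(oracle["slope"]), tolerance = 1e-10)
  expect_equal(fit$intercept, unname(oracle["intercept"]), tolerance = 1e-10)
  expect_equal(nrow(fit$removed), 0L)
})

test_that("iterative Cook's-distance pruning removes exactly the planted outliers", {
  # gross outliers at high leverage (extreme host durations, far off the
  # line), the configuration in which Cook pruning is well identified
  out <- data.frame(x = c(120, 150, 180),
                    y = 0.007 * c(120, 150, 180) + c(0.5, -0.5, 0.5))
  pr <- make_regression_pairs(23, slope = 0.007, intercept = 0,
                              noise_sd = 0.01, outliers = out,
                              x_range = c(1, 70), seed = 71)
  fit <- fit_codivergence(pr, cook_factor = 3)
  expect_equal(nrow(fit$removed), 3L)
  expect_true(all(grepl("^outlier_", fit$removed$virus_branch)))
  expect_equal(fit$n_used, 23L)
  # the generating slope lies inside the fit's own 95% CI
  tq <- qt(0.975, fit$df)
  expect_true(abs(fit$slope - 0.007) < tq * fit$slope_se)
  # ledger bookkeeping: removals + retained = input
  expect_equal(fit$n_used + nrow(fit$removed), nrow(pr))
})

test_that("pruning always terminates and degenerate fits are refused", {
  pr <- make_regression_pairs(10, slope = 0.01, noise_sd = 0.002, seed = 81)
  fit <- fit_codivergence(pr)
  expect_lte(nrow(fit$removed), nrow(pr))
  expect_error(fit_codivergence(pr[1:3, ]), "at least 4")
  flat <- data.frame(host_duration = rep(5, 6),
                     virus_branch_length = rnorm(6))
  expect_error(fit_codivergence(flat), "variance")
})

test_that("node dating inverts the regression and subtracts from the calibration", {
  pairs <- data.frame(host_duration = c(2, 4, 6, 8, 10),
                      virus_branch_length = 0.01 * c(2, 4, 6, 8, 10))
  fit <- fit_codivergence(pairs)
  nd <- estimate_node_date(fit, branch_length = 0.05, calibration_age = 100)
  expect_equal(nd$duration, 5, tolerance = 1e-9)
  expect_equal(nd$point, 95, tolerance = 1e-9)
  expect_true(nd$ci95[1] <= nd$point && nd$point <= nd$ci95[2])

  # zero branch length with zero intercept dates the node at the calibration
  nd0 <- estimate_node_date(fit, 0, 101.1)
  expect_equal(nd0$point, 101.1, tolerance = 1e-9)

  # dates are non-increasing in branch length
  bl <- seq(0, 0.08, by = 0.02)
  pts <- vapply(bl, function(b) estimate_node_date(fit, b, 100)$point,
                numeric(1))
  expect_true(all(diff(pts) <= 0))
})

test_that("non-informative fits cannot be inverted", {
  pairs <- make_regression_pairs(10, slope = -0.01, intercept = 0.5,
                                 noise_sd = 0.001, seed = 91)
  fit <- fit_codivergence(pairs, cook_factor = Inf)
  expect_error(estimate_node_date(fit, 0.05, 100), "non-informative")
})

test_that("missing host clade ages are reported by name", {
  ht <- ape::read.tree(text = "(((a:10,b:10):10,c:20):10,d:30);")
  vt <- ape::read.tree(text = "(((A:0.1,B:0.1):0.1,C:0.2):0.1,D:0.3);")
  as <- tip_association(c("A", "B", "C", "D"), c("a", "b", "c", "d"))
  r <- reconcile(vt, ht, as)
  partial <- node_ages("a;b", 10)   # root and a+b+c clades missing
  expect_error(extract_branch_pairs(r, vt, ht, partial), "no age entry")
})
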