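test_that("analysis window keeps exactly the closed-interval rows", {
  tr <- filtration_trace("s1", times = 0:7,
                         heights = c(250, 230, 210, 180, 120, 100, 80, 50))
  win <- apply_window(tr)
  keep_brute <- which(tr$height_mm >= 100 & tr$height_mm <= 210)
  expect_equal(win$height_mm, tr$height_mm[keep_brute])
  expect_true(all(c(210, 100) %in% win$height_mm))  # boundaries retained
  tr_in <- filtration_trace("s2", 0:4, c(205, 180, 150, 120, 101))
  expect_equal(apply_window(tr_in)$height_mm, tr_in$height_mm)
})

test_that("objective is zero on the generating curve and positive elsewhere", {
  tr <- gen_filtration_trace(800, n_points = 30, noise_sd_rel = 0, seed = 1)
  expect_equal(filtration_objective(tr, 800), 0, tolerance = 1e-20)
  expect_gt(filtration_objective(tr, 700), 0)
  expect_gt(filtration_objective(tr, 900), 0)
})

test_that("objective equals a hand-computed mean squared relative residual", {
  # 3-point toy trace, all in-window; model H(t) = 210 exp(-r t)
  k <- 1000
  r <- 1000 * 0.25 * 9.81e-6 / 2
  t_i <- c(0, 120, 300)
  h_exp <- c(208, 185, 150)
  h_mod <- 210 * exp(-r * t_i)
  by_hand <- mean((1 - h_mod / h_exp)^2)
  tr <- filtration_trace("toy", t_i, h_exp)
  expect_equal(filtration_objective(tr, k), by_hand, tolerance = 1e-14)
})

test_that("objective errors when nothing is inside the window", {
  tr <- filtration_trace("low", 0:2, c(90, 80, 70))
  expect_error(filtration_objective(tr, 100), "no-usable-points")
  expect_error(fit_permeability(tr), "no-usable-points")
})

test_that("noiseless traces recover K essentially exactly", {
  for (k_true in c(20, 500, 8000)) {
    tr <- gen_filtration_trace(k_true, n_points = 50, noise_sd_rel = 0)
    fit <- fit_permeability(tr)
    expect_equal(fit$k_hat, k_true, tolerance = 1e-6)
    expect_true(fit$converged)
    expect_lt(fit$objective_value, 1e-15)
  }
})

test_that("the fitted K is the global minimizer found by dense grid search", {
  tr <- gen_filtration_trace(500, n_points = 50, noise_sd_rel = 0.01,
                             seed = 7)
  fit <- fit_permeability(tr)
  k_grid <- grid_search_k(tr, 50, 5000)
  expect_equal(fit$k_hat, k_grid, tolerance = 2e-3)
  expect_lte(fit$objective_value,
             filtration_objective(tr, k_grid) + 1e-12)
  expect_equal(fit$k_hat / 500, 1, tolerance = 0.05)
})

test_that("objective grid scan is unimodal for a noiseless trace", {
  tr <- gen_filtration_trace(1000, n_points = 40, noise_sd_rel = 0)
  ks <- seq(200, 5000, length.out = 400)
  obj <- vapply(ks, function(k) filtration_objective(tr, k), 1)
  sign_changes <- sum(diff(sign(diff(obj))) != 0)
  expect_lte(sign_changes, 1)  # one interior minimum, no other turning point
})

test_that("constant and rising traces clamp to K = 0 with a warning record", {
  tr <- filtration_trace("flat", c(0, 60, 120), c(205, 205, 205))
  fit <- fit_permeability(tr)
  expect_identical(fit$k_hat, 0)
  expect_true(fit$converged)
  expect_match(fit$warning, "non-decaying")
})

test_that("fitting is invariant to time origin and consistent height rescale", {
  tr <- gen_filtration_trace(600, n_points = 40, noise_sd_rel = 0.01,
                             seed = 3)
  k0 <- fit_permeability(tr)$k_hat
  shifted <- tr
  shifted$time_s <- shifted$time_s + 1234
  expect_equal(fit_permeability(shifted)$k_hat, k0, tolerance = 1e-9)
  s <- 0.01  # heights in different units, window and H0 rescaled with them
  geom_s <- device_geometry(initial_height_mm = 210 * s,
                            window_mm = c(100, 210) * s)
  scaled <- tr
  scaled$height_mm <- scaled$height_mm * s
  expect_equal(fit_permeability(scaled, geom = geom_s)$k_hat, k0,
               tolerance = 1e-6)
})

test_that("parameter recovery holds over 200 noisy traces", {
  set.seed(2024)
  rel_err <- replicate(200, {
    k_true <- 10^runif(1, 1, 4)
    tr <- gen_filtration_trace(k_true, n_points = 50, noise_sd_rel = 0.01)
    abs(fit_permeability(tr)$k_hat / k_true - 1)
  })
  expect_lt(median(rel_err), 0.02)
  expect_lt(quantile(rel_err, 0.95), 0.10)
})

test_that("reliability summary reports zero CV for identical repeats", {
  est <- data.frame(sample_id = rep(c("a", "b"), each = 3),
                    k_mm4_per_Ns = rep(c(100, 200), each = 3))
  rs <- reliability_summary(est)
  expect_equal(rs$per_sample$cv, c(0, 0))
  expect_equal(rs$n_samples, 2)
  expect_error(reliability_summary(data.frame(sample_id = "a",
                                              k_mm4_per_Ns = 1)),
               "insufficient-repeats")
})

test_that("noiseless reliability protocol has CV = 0 at every level", {
  traces <- gen_reliability_traces(k_true = 1000, n_repeats = 5,
                                   n_samples = 3, noise_sd_rel = 0, seed = 1)
  fits <- fit_permeability_table(traces)
  rs <- reliability_summary(fits[, c("sample_id", "k_mm4_per_Ns")])
  expect_equal(rs$per_sample$cv, rep(0, 3), tolerance = 1e-8)
  expect_equal(rs$across_sample_cv, 0, tolerance = 1e-8)
})

test_that("group comparison flags separated groups and not identical ones", {
  same <- data.frame(
    sample_id = sprintf("s%d", 1:8),
    group = rep(c("fresh", "decellularized"), each = 4),
    k_mm4_per_Ns = c(1, 2, 3, 4, 1.5, 2.5, 3.5, 4.5))
  res_same <- compare_permeability_groups(same)
  expect_gt(res_same$p, 0.05)
  expect_equal(res_same$stars, "ns")

  sim <- gen_group_permeabilities(seed = 11)
  fits <- fit_permeability_table(sim$traces)
  cmp <- compare_permeability_groups(fits)
  dvf <- cmp[cmp$group_a == "decellularized" & cmp$group_b == "fresh", ]
  expect_lt(dvf$p, 0.05)
  # sample medians follow the generated ordering
  med <- with(cmp[cmp$group_a == "decellularized" &
                    cmp$group_b == "fresh", ], c(median_a, median_b))
  expect_gt(med[1], med[2])
  expect_error(compare_permeability_groups(same[1:4, ]), "insufficient-n")
})
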