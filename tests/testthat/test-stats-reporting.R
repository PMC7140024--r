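test_that("star labels follow the three strict thresholds", {
  expect_equal(star_label(0.0005), "***")
  expect_equal(star_label(0.005), "**")
  expect_equal(star_label(0.03), "*")
  expect_equal(star_label(c(0.001, 0.01, 0.05)), c("**", "*", "ns"))
  expect_equal(star_label(0.5), "ns")
  expect_error(star_label(1.2), "invalid-p")
  expect_error(star_label(-0.1), "invalid-p")
  # monotone non-increasing severity in p
  ps <- sort(runif(50))
  ranks <- match(star_label(ps), c("***", "**", "*", "ns"))
  expect_true(all(diff(ranks) >= 0))
})

test_that("exact Mann-Whitney p matches full enumeration on small samples", {
  set.seed(99)
  fixtures <- list(
    list(a = c(1, 2, 3), b = c(10, 11, 12)),        # complete separation
    list(a = c(1, 5, 9), b = c(2, 6, 10)),          # interleaved
    list(a = c(3, 1, 8, 12), b = c(2, 9, 4)),       # n = 4 vs 3
    list(a = rnorm(5), b = rnorm(5) + 1),
    list(a = rnorm(6), b = rnorm(6)),
    list(a = rnorm(4), b = rnorm(6) + 2)
  )
  for (fx in fixtures) {
    res <- two_group_test(fx$a, fx$b, parametric = FALSE)
    expect_equal(res$p_value, mw_enum_p(fx$a, fx$b), tolerance = 1e-12)
  }
  # the separated 3-vs-3 case has p = 2/20 by enumeration
  expect_equal(two_group_test(c(1, 2, 3), c(10, 11, 12),
                              parametric = FALSE)$p_value, 0.1)
})

test_that("identical samples give p = 1 and label ns", {
  res <- two_group_test(c(1, 2, 3), c(1, 2, 3), parametric = FALSE)
  expect_equal(res$p_value, 1)
  expect_equal(res$stars, "ns")
})

test_that("t-test holds its nominal type-I error on null simulations", {
  set.seed(314)
  rejections <- mean(replicate(1000, {
    two_group_test(rnorm(10), rnorm(10), parametric = TRUE)$p_value < 0.05
  }))
  expect_gt(rejections, 0.035)
  expect_lt(rejections, 0.065)
})

test_that("two-group test validates inputs and exposes the Welch toggle", {
  expect_error(two_group_test(c(1, 2), c(1, 2, 3)), "insufficient-n")
  a <- c(1, 2, 3, 4, 10); b <- c(2.2, 3.1, 4.5)
  student <- two_group_test(a, b, parametric = TRUE)
  welch <- two_group_test(a, b, parametric = TRUE, welch = TRUE)
  expect_equal(student$method, "t_test_two_sided")
  expect_equal(welch$method, "welch_t_two_sided")
  expect_false(isTRUE(all.equal(student$p_value, welch$p_value)))
  # cross-check Student's t against the closed form
  sp2 <- ((length(a) - 1) * var(a) + (length(b) - 1) * var(b)) /
    (length(a) + length(b) - 2)
  t_manual <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / length(a) + 1 / length(b)))
  expect_equal(unname(student$statistic), t_manual, tolerance = 1e-12)
})

test_that("multi-group omnibus and Bonferroni post hoc behave as defined", {
  g <- list(a = c(1, 2, 3, 4), b = c(1, 2, 3, 4), c = c(1, 2, 3, 4))
  res <- multi_group_test(g, parametric = TRUE)
  expect_gt(res$omnibus$p_value, 0.99)

  set.seed(5)
  shifted <- list(a = rnorm(8), b = rnorm(8), c = rnorm(8) + 4)
  par_res <- multi_group_test(shifted, parametric = TRUE)
  expect_lt(par_res$omnibus$p_value, 0.001)
  expect_equal(par_res$pairwise$p_adj,
               pmin(1, par_res$pairwise$p_raw * 3))  # Bonferroni definition
  expect_true(all(par_res$pairwise$p_adj >= par_res$pairwise$p_raw))
  flagged <- par_res$pairwise$p_adj < 0.05
  involves_c <- par_res$pairwise$group_a == "c" |
    par_res$pairwise$group_b == "c"
  expect_equal(flagged, involves_c)  # only the shifted pairs light up
  expect_error(multi_group_test(shifted[1:2]), "insufficient-n")
})

test_that("Dunn post hoc matches a by-hand rank computation", {
  set.seed(17)
  g <- list(a = rnorm(8), b = rnorm(8), c = rnorm(8) + 4)
  res <- multi_group_test(g, parametric = FALSE)
  expect_equal(res$omnibus$method, "kruskal_dunn")
  # by-hand z for the a-vs-c pair from the pooled ranking (no ties)
  values <- unlist(g)
  r <- rank(values)
  N <- length(values)
  mr <- tapply(r, rep(names(g), lengths(g)), mean)
  se <- sqrt(N * (N + 1) / 12 * (1 / 8 + 1 / 8))
  z_ac <- (mr[["a"]] - mr[["c"]]) / se
  row_ac <- res$pairwise[res$pairwise$group_a == "a" &
                           res$pairwise$group_b == "c", ]
  expect_equal(row_ac$statistic, z_ac, tolerance = 1e-12)
  expect_equal(row_ac$p_adj, min(1, 2 * pnorm(-abs(z_ac)) * 3),
               tolerance = 1e-12)
  flagged <- res$pairwise$p_adj < 0.05
  involves_c <- res$pairwise$group_a == "c" | res$pairwise$group_b == "c"
  expect_equal(flagged, involves_c)
})

test_that("comparisons table flattens results in the reporting schema", {
  r1 <- two_group_test(c(1, 2, 3), c(10, 11, 12), comparison = "x vs y")
  tab <- comparisons_table(r1)
  expect_equal(names(tab), c("comparison", "method", "statistic", "p",
                             "stars"))
  expect_equal(tab$comparison, "x vs y")
})
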