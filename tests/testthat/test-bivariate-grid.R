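test_that("grid designs use scaled equally spaced times and the stated retention rules", {
  bt <- build_times_Z(6, 0)
  expect_equal(bt$times, c(-1, -0.6, -0.2, 0.2, 0.6, 1))
  expect_equal(bt$Z2, bt$Z1)   # complete data: identical designs

  bt_d <- build_times_Z(6, 1/3, "dropout")
  expect_equal(bt_d$keep2, 1:4)   # ni2 = (2/3) ni1
  expect_equal(bt_d$Z2, bt_d$Z1[1:4, ])

  bt_r <- build_times_Z(9, 2/3, "random", seed = 5)
  expect_equal(length(bt_r$keep2), 3L)
  expect_identical(bt_r$keep2, build_times_Z(9, 2/3, "random", seed = 5)$keep2)
  expect_error(build_times_Z(6, 0.95), "fully missing")
})

test_that("the plausibility mask excludes only large opposite-sign pairs", {
  expect_true(likely_mask(0.9, 0.9))
  expect_false(likely_mask(-0.9, 0.9))
  expect_true(likely_mask(-0.3, 0.1))
  expect_true(likely_mask(-0.5, 0.3))
  expect_false(likely_mask(0.5, -0.5))
  expect_equal(likely_mask(c(0.9, -0.9), c(0.9, 0.9)), c(TRUE, FALSE))
})

test_that("separable truth gives exactly full efficiency in every cell", {
  for (case in c("A", "B", "C")) {
    r <- evaluate_cell(grid_cell(case, 0, 0, 0.5, n1 = 6, pmiss = 1/3,
                                 pattern = "dropout"))
    expect_equal(r$ratio_b2, 1, tolerance = 1e-10)
  }
})

test_that("the lean grid evaluator agrees with the generic efficiency module", {
  cells <- list(grid_cell("A", 0.9, 0.9, 0, n1 = 6, pmiss = 0),
                grid_cell("B", 0.7, -0.3, -0.5, n1 = 9, pmiss = 1/3,
                          pattern = "dropout"),
                grid_cell("C", -0.5, -0.7, 0.5, n1 = 6, pmiss = 2/3,
                          pattern = "random", pattern_seed = 99L))
  for (cl in cells) {
    r <- evaluate_cell(cl, n_pattern_draws = 3)
    D <- build_bivariate_D(cl$case, cl$rho_b, cl$rho_k, cl$rho_k)
    R <- build_bivariate_R(cl$case, cl$rho_r)
    comp <- covariance_components(D, R)
    draws <- if (cl$pattern == "random" && cl$pmiss > 0) 1:3 else 1L
    mse_C <- mse_S <- 0
    for (d in draws) {
      seed <- mlmmeff:::derive_seed(cl$pattern_seed, 0L, d)
      bt <- build_times_Z(cl$n1, cl$pmiss, cl$pattern, seed)
      s <- subject_design("s", list(
        marker_design("m1", bt$times, bt$Z1, bt$Z1),
        marker_design("m2", bt$times[bt$keep2], bt$Z2, bt$Z2)))
      dC <- random_effects_mse(s, comp, "combined")
      dS <- random_effects_mse(s, comp, "separated")
      mse_C <- mse_C + sum(dC$per_coordinate[3:4]) / length(draws)
      mse_S <- mse_S + sum(dS$per_coordinate[3:4]) / length(draws)
    }
    expect_equal(r$ratio_b2, mse_C / mse_S, tolerance = 1e-10)
  }
})

test_that("grid results respect the BLUP bound and summarize over likely cells", {
  spec <- default_grid_spec(cases = "B", pmiss = c(0, 1/3), n1 = 6,
                            rho_k = 0, rho_b = c(-0.9, -0.5, 0.5, 0.9),
                            rho_r = c(-0.9, 0.5, 0.9), pattern = "dropout")
  res <- run_grid(spec, n_pattern_draws = 1)
  expect_equal(nrow(res), nrow(spec))
  expect_true(all(res$ratio_b2 > 0 & res$ratio_b2 <= 1 + 1e-9))
  sm <- summarize_grid(res)
  expect_true(all(c("min", "q25", "median", "q75", "max") %in% names(sm)))
  expect_true(all(sm$min <= sm$q25 & sm$q25 <= sm$median & sm$median <= sm$max))
  expect_equal(sum(sm$n_cells), sum(res$likely))
  hm <- heatmap_long(res, n1 = 6, rho_k = 0)
  expect_equal(nrow(hm), nrow(res))
  expect_error(summarize_grid(res[0, ]), "empty")
})

test_that("restricting the grid to zero correlations collapses every summary to one", {
  spec <- default_grid_spec(rho_b = 0, rho_r = 0, rho_k = 0, n1 = 6,
                            pattern = "dropout")
  res <- run_grid(spec, n_pattern_draws = 1)
  expect_equal(res$ratio_b2, rep(1, nrow(res)), tolerance = 1e-10)
})

test_that("inefficiency grows with missingness and is slightly larger under drop-out", {
  res <- full_default_grid()
  lk <- res[res$likely, ]
  for (case in c("A", "B", "C")) for (pat in c("random", "dropout")) {
    means <- tapply(lk$ratio_b2[lk$case == case & lk$pattern == pat],
                    lk$pmiss[lk$case == case & lk$pattern == pat], mean)
    expect_true(all(diff(means[order(as.numeric(names(means)))]) <= 0))
  }
  m_drop <- mean(lk$ratio_b2[lk$pattern == "dropout" & lk$pmiss > 0])
  m_rand <- mean(lk$ratio_b2[lk$pattern == "random" & lk$pmiss > 0])
  expect_lte(m_drop, m_rand + 0.02)
})
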