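scalar_subject <- function() {
  subject_design("s1", list(marker_design(
    "m1", 0, matrix(1, dimnames = list(NULL, "intercept")),
    matrix(1, dimnames = list(NULL, "intercept")))))
}

test_that("scalar shrinkage case reproduces the textbook decomposition", {
  s <- scalar_subject()
  comp <- covariance_components(matrix(1), matrix(1), q = 1)
  expect_equal(blup_map(s, comp, "combined")[1, 1], 0.5)
  d <- random_effects_mse(s, comp, "combined")
  expect_equal(d$mse, 0.5)
  expect_equal(d$squared_bias, 0.25)
  expect_equal(d$variance, 0.25)

  # zero random-effects variance in the working model: total shrinkage
  comp0 <- covariance_components(matrix(0), matrix(1), q = 1)
  w0 <- working_model("combined", comp0)
  expect_equal(blup_map(s, comp, w0)[1, 1], 0)
})

test_that("GLS map reduces to OLS under identity weights and decouples when separated", {
  set.seed(21)
  tt <- sort(runif(5))
  X <- cbind(intercept = 1, slope = tt)
  s <- subject_design("s", list(marker_design("m1", tt, X, X)))
  comp <- covariance_components(matrix(0, 2, 2), matrix(1), q = 2)
  gm <- gls_map(list(s), comp, working_model("combined", comp))
  expect_equal(unname(gm$A[[1]]), unname(solve(crossprod(X), t(X))))

  # separated working model: block-diagonal map over measures
  cfg <- random_config(5, K = 2, m = 3)
  gm_s <- gls_map(cfg$subjects, cfg$components, "separated")
  p_k <- ncol(cfg$subjects[[1]]$markers[[1]]$X)
  expect_equal(gm_s$G_inv[seq_len(p_k), p_k + seq_len(p_k)],
               matrix(0, p_k, p_k), ignore_attr = TRUE, tolerance = 1e-12)

  # unbiasedness: sum_i A_i X_i = I for both working models
  for (w in c("combined", "separated")) {
    gm_w <- gls_map(cfg$subjects, cfg$components, w)
    S <- Reduce(`+`, Map(function(A, ci) A %*% ci$X, gm_w$A, gm_w$ctx))
    expect_lt(max(abs(S - diag(nrow(S)))), 1e-8)
  }

  # dense normal-equation oracle on a 3-subject toy
  G <- matrix(0, ncol(gm_s$G_inv), ncol(gm_s$G_inv))
  wk <- working_from_truth(cfg$components, "combined")
  gm_c <- gls_map(cfg$subjects, cfg$components, wk)
  for (i in 1:3) {
    des <- assemble_block_design(cfg$subjects[[i]])
    V <- des$Z %*% cfg$components$D %*% t(des$Z) +
      build_residual_cov(cfg$subjects[[i]], cfg$components$R)
    G <- G + t(des$X) %*% solve(V, des$X)
  }
  expect_equal(gm_c$G_inv, solve(G), ignore_attr = TRUE, tolerance = 1e-8)
})

test_that("separated fixed effects are fully efficient only under shared designs", {
  # identical X across measures and subjects, Z a common sub-matrix, complete
  # data: ratio exactly 1
  for (seed in 1:5) {
    set.seed(seed)
    tt <- sort(runif(5, 0, 10)); x_extra <- rnorm(5)
    X <- cbind(intercept = 1, slope = tt, x = x_extra)
    Z <- X[, 1:2]
    subs <- lapply(1:4, function(i)
      subject_design(paste0("s", i), list(marker_design("m1", tt, X, Z),
                                          marker_design("m2", tt, X, Z))))
    comp <- covariance_components(random_psd(4, seed), random_psd(2, seed + 50))
    fC <- fixed_effects_mse(subs, comp, "combined")
    fS <- fixed_effects_mse(subs, comp, "separated")
    expect_equal(mse_ratio(fC, fS), 1, tolerance = 1e-10)
    expect_equal(fC$squared_bias, 0)
    expect_equal(fS$squared_bias, 0)
  }

  # K = 1: separated and combined are the same model
  cfg1 <- random_config(31, K = 1, m = 3)
  f1C <- fixed_effects_mse(cfg1$subjects, cfg1$components, "combined")
  f1S <- fixed_effects_mse(cfg1$subjects, cfg1$components, "separated")
  expect_equal(mse_ratio(f1C, f1S), 1, tolerance = 1e-12)

  # working = true: variance equals the GLS covariance trace
  gm <- gls_map(cfg1$subjects, cfg1$components, "combined")
  expect_equal(f1C$variance, sum(diag(gm$G_inv)), tolerance = 1e-10)
})

test_that("zero cross-measure covariance makes all three ratios one", {
  cfg <- random_config(9, K = 2, m = 3)
  comp0 <- separate_components(cfg$components)
  for (bk in c(TRUE, FALSE)) {
    bC <- random_effects_mse(cfg$subjects, comp0, "combined", beta_known = bk)
    bS <- random_effects_mse(cfg$subjects, comp0, "separated", beta_known = bk)
    expect_equal(mse_ratio(bC, bS), 1, tolerance = 1e-10)
    yC <- predicted_values_mse(cfg$subjects, comp0, "combined", beta_known = bk)
    yS <- predicted_values_mse(cfg$subjects, comp0, "separated", beta_known = bk)
    expect_equal(mse_ratio(yC, yS), 1, tolerance = 1e-10)
  }
  fC <- fixed_effects_mse(cfg$subjects, comp0, "combined")
  fS <- fixed_effects_mse(cfg$subjects, comp0, "separated")
  expect_equal(mse_ratio(fC, fS), 1, tolerance = 1e-10)
})

test_that("the combined working model is MSE-optimal for random effects", {
  for (seed in c(2, 7, 13, 28)) {
    cfg <- random_config(seed, K = sample(c(2, 5), 1), m = 2)
    for (bk in c(TRUE, FALSE)) {
      bC <- random_effects_mse(cfg$subjects, cfg$components, "combined", bk)
      bS <- random_effects_mse(cfg$subjects, cfg$components, "separated", bk)
      expect_lte(bC$mse, bS$mse + 1e-9)
    }
  }
})

test_that("closed-form measure-2 MSEs match the frozen million-draw oracle", {
  # case A, rho_b = rho_r = 0.9, rho_k = 0, n1 = 6, drop-out, pmiss = 2/3;
  # frozen empirical values from an independent 1e6-draw simulation:
  # mse_C = 0.377795 (se 0.000390), mse_S = 1.322634 (se 0.001590)
  s <- bivar_subject(6, 2/3, "dropout")
  comp <- covariance_components(build_bivariate_D("A", 0.9, 0, 0),
                                build_bivariate_R("A", 0.9))
  dC <- random_effects_mse(s, comp, "combined")
  dS <- random_effects_mse(s, comp, "separated")
  mse_C <- sum(dC$per_coordinate[3:4])
  mse_S <- sum(dS$per_coordinate[3:4])
  expect_lt(abs(mse_C - 0.377795), 4 * 0.000390)
  expect_lt(abs(mse_S - 1.322634), 4 * 0.001590)
})

test_that("prediction MSE reduces to fixed-effect prediction variance when D is zero", {
  cfg <- random_config(17, K = 2, m = 3)
  comp0 <- covariance_components(0 * cfg$components$D, cfg$components$R)
  yC <- predicted_values_mse(cfg$subjects, comp0, "combined", beta_known = FALSE)
  gm <- gls_map(cfg$subjects, comp0, "combined")
  expected <- 0
  # with D = 0 the BLUP map is 0, so the yhat error is X_i (beta_hat - beta);
  # accumulate the trace over the shared beta_hat covariance
  for (i in seq_along(gm$A)) {
    for (j in seq_along(gm$A)) {
      XAj <- gm$ctx[[i]]$X %*% gm$A[[j]]
      expected <- expected + sum((XAj %*% gm$ctx[[j]]$V_t) * XAj)
    }
  }
  expect_equal(yC$mse, expected, tolerance = 1e-8)
  expect_equal(yC$squared_bias, 0, tolerance = 1e-10)
})

test_that("ratio selection, aggregation options and degeneracies behave", {
  cfg <- random_config(23, K = 2, m = 3)
  bC <- random_effects_mse(cfg$subjects, cfg$components, "combined")
  bS <- random_effects_mse(cfg$subjects, cfg$components, "separated")
  expect_equal(mse_ratio(bC, bC), 1)
  r_all <- mse_ratio(bC, bS)
  r_m1 <- mse_ratio(bC, bS, measure = "m1")
  r_m2 <- mse_ratio(bC, bS, measure = "m2")
  expect_true(r_all > 0 && r_all <= 1 + 1e-9)
  # pooled ratio lies between the measure-wise ratios
  expect_gte(r_all, min(r_m1, r_m2) - 1e-12)
  expect_lte(r_all, max(r_m1, r_m2) + 1e-12)
  # effect selection picks the right coordinates
  r_int <- mse_ratio(bC, bS, effect = "intercept")
  num <- sum(bC$per_coordinate[grep(":intercept$", bC$coordinate_labels)])
  den <- sum(bS$per_coordinate[grep(":intercept$", bS$coordinate_labels)])
  expect_equal(r_int, num / den)
  # mean of ratios uses the per-subject traces
  r_mor <- mse_ratio(bC, bS, method = "mean_of_ratios")
  expect_equal(r_mor, mean(rowSums(bC$per_subject) / rowSums(bS$per_subject)))
  expect_error(mse_ratio(bC, bS, measure = "nope"), "empty")
})

test_that("efficiency table reports both models for all estimands", {
  cfg <- random_config(41, K = 2, m = 2)
  tab <- efficiency_table(cfg$subjects, cfg$components)
  expect_equal(nrow(tab), 6L)
  expect_true(all(tab$mse >= 0) && all(abs(tab$mse - tab$bias2 - tab$var) < 1e-8))
  expect_equal(tab$bias2[tab$estimand == "beta"], c(0, 0))
})
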