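test_that("block design assembly is a direct sum with measure-major ordering", {
  t1 <- c(0, 1); t2 <- 0.5
  m1 <- marker_design("m1", t1, cbind(1, t1), cbind(1, t1))
  m2 <- marker_design("m2", t2, cbind(1, t2), cbind(1, t2))
  s <- subject_design("s1", list(m1, m2))
  expect_equal(s$n_i, 3L)
  des <- assemble_block_design(s)
  expect_equal(dim(des$X), c(3L, 4L))
  expect_equal(des$X[1:2, 3:4], matrix(0, 2, 2), ignore_attr = TRUE)
  expect_equal(des$X[3, ], c(0, 0, 1, 0.5), ignore_attr = TRUE)

  # K = 1 leaves the block unchanged
  s1 <- subject_design("s1", list(m1))
  expect_equal(unname(assemble_block_design(s1)$X), unname(cbind(1, t1)))

  # Kronecker-sum contract: X_i b stacks the per-measure products
  set.seed(4)
  for (rep in 1:5) {
    b <- rnorm(4)
    expect_equal(as.numeric(des$X %*% b),
                 c(as.numeric(m1$X %*% b[1:2]), as.numeric(m2$X %*% b[3:4])))
  }
  expect_error(subject_design("s", list()), "no measures")
})

test_that("bivariate case-study design with 33% missingness gives a 10 x 4 Z", {
  s <- bivar_subject(n1 = 6, pmiss = 1/3)
  expect_equal(dim(assemble_block_design(s)$Z), c(10L, 4L))
})

test_that("bivariate D construction honours the scenario diagonals and PSD repair", {
  expect_equal(build_bivariate_D("A", 0, 0, 0), diag(4))
  DC <- build_bivariate_D("C", 0, 0, 0.5)
  expect_equal(diag(DC), c(1, 1, 1, 4))
  expect_equal(DC[3, 4], 0.5 * sqrt(4))
  expect_equal(DC[1, 3], 0)

  # indefinite raw construction: frozen clip-and-rescale oracle
  Drep <- build_bivariate_D("A", 0.9, -0.5, -0.5)
  oracle <- matrix(c(1, -0.13207547, 0.43396226, 0.43396226,
                     -0.13207547, 1, 0.43396226, 0.43396226,
                     0.43396226, 0.43396226, 1, -0.13207547,
                     0.43396226, 0.43396226, -0.13207547, 1), 4, 4)
  expect_equal(Drep, oracle, tolerance = 1e-7)
  expect_gte(min(eigen(Drep, symmetric = TRUE, only.values = TRUE)$values), -1e-12)

  # the whole default correlation grid yields PSD matrices with unit-ish diag
  for (case in c("A", "B", "C")) for (rb in c(-0.9, -0.3, 0.5, 0.9))
    for (rk in c(-0.5, 0, 0.5)) {
      D <- build_bivariate_D(case, rb, rk, rk)
      expect_gte(min(eigen(D, symmetric = TRUE, only.values = TRUE)$values), -1e-12)
      expect_equal(diag(D), if (case == "C") c(1, 1, 1, 4) else rep(1, 4))
    }
  expect_error(build_bivariate_D("A", 1.2, 0, 0))
})

test_that("bivariate R construction matches its definition", {
  expect_equal(build_bivariate_R("A", 0.7), matrix(c(1, .7, .7, 1), 2))
  expect_equal(build_bivariate_R("B", 0.5), matrix(c(1, 1, 1, 4), 2))
  expect_equal(build_bivariate_R("B", -0.9), matrix(c(1, -1.8, -1.8, 4), 2))
})

test_that("residual covariance links only simultaneous cross-measure observations", {
  t12 <- c(0, 1)
  m1 <- marker_design("m1", t12, cbind(1, t12), cbind(1, t12))
  m2 <- marker_design("m2", t12, cbind(1, t12), cbind(1, t12))
  R <- matrix(c(1, .7, .7, 1), 2)
  Sig <- build_residual_cov(subject_design("s", list(m1, m2)), R)
  expect_equal(Sig[1, 3], 0.7); expect_equal(Sig[2, 4], 0.7)
  expect_equal(Sig[1, 4], 0); expect_equal(Sig[1, 2], 0)
  expect_equal(diag(Sig), rep(1, 4))

  # disjoint times: block diagonal
  m2b <- marker_design("m2", c(2, 3), cbind(1, c(2, 3)), cbind(1, c(2, 3)))
  Sig2 <- build_residual_cov(subject_design("s", list(m1, m2b)), R)
  expect_equal(Sig2, diag(4))

  # K = 1: scaled identity
  Sig1 <- build_residual_cov(subject_design("s", list(m1)), matrix(2))
  expect_equal(Sig1, 2 * diag(2))
})

test_that("marginal covariance matches the direct formula and simulation", {
  s <- bivar_subject(6, 0)
  D <- build_bivariate_D("A", 0.5, 0, 0)
  R <- build_bivariate_R("A", 0.5)
  comp <- covariance_components(D, R)
  mc <- marginal_cov(s, comp)
  des <- assemble_block_design(s)
  V_direct <- des$Z %*% D %*% t(des$Z) + build_residual_cov(s, R)
  expect_equal(mc$V, V_direct, ignore_attr = TRUE)
  expect_lt(max(abs(mc$W %*% mc$V - diag(nrow(mc$V)))), 1e-8)

  # D = 0 reduces to the residual covariance
  comp0 <- covariance_components(0 * D, R)
  expect_equal(marginal_cov(s, comp0)$V, build_residual_cov(s, R),
               ignore_attr = TRUE)

  # degenerate case errors
  comp_bad <- covariance_components(0 * D, 0 * R)
  expect_error(marginal_cov(s, comp_bad), "degenerate")

  # V equals the empirical covariance of simulated residuals Y - X beta
  for (seed in 1:5) {
    cfg <- random_config(seed, K = 2, m = 1)
    sub <- cfg$subjects[[1]]
    mcv <- marginal_cov(sub, cfg$components)
    set.seed(seed + 100)
    n <- nrow(mcv$V); reps <- 1e5
    Dh <- t(chol(cfg$components$D + 1e-12 * diag(nrow(cfg$components$D))))
    Sh <- t(chol(build_residual_cov(sub, cfg$components$R) + 1e-12 * diag(n)))
    Zm <- assemble_block_design(sub)$Z
    Y <- matrix(rnorm(reps * ncol(Dh)), reps) %*% t(Dh) %*% t(Zm) +
         matrix(rnorm(reps * n), reps) %*% t(Sh)
    emp <- crossprod(Y) / reps
    se <- sqrt((mcv$V^2 + tcrossprod(diag(mcv$V))) / reps)  # MC se of cov entries
    expect_lt(max(abs(emp - mcv$V) / se), 4)
  }
})

test_that("psd repair clips eigenvalues while preserving the diagonal", {
  M <- matrix(c(1, 1.2, 1.2, 1), 2)
  expect_equal(psd_repair(M), matrix(1, 2, 2))
  expect_equal(psd_repair(diag(3)), diag(3))

  # idempotence and diagonal preservation on a larger indefinite matrix
  set.seed(8)
  A <- matrix(rnorm(36), 6); A <- (A + t(A)) / 2; diag(A) <- abs(diag(A)) + 1
  Arep <- psd_repair(A)
  expect_equal(diag(Arep), diag(A), tolerance = 1e-12)
  expect_gte(min(eigen(Arep, symmetric = TRUE, only.values = TRUE)$values), -1e-12)
  expect_equal(psd_repair(Arep), Arep, tolerance = 1e-12)

  # PSD-representable construction is untouched when already PSD
  D_ok <- build_bivariate_D("A", 0.3, 0.5, 0.5)
  expect_equal(D_ok[1, 2], 0.5)
  expect_equal(D_ok[1, 3], 0.3)

  expect_error(psd_repair(matrix(c(1, 2, 0, 1), 2)), "symmetric")
})

test_that("separating components zeroes exactly the cross-measure entries", {
  comp <- scleroderma_components()
  sep <- separate_components(comp)
  expect_equal(sep$R, diag(diag(comp$R), 5), ignore_attr = TRUE)
  off <- sep$D
  for (k in 1:5) off[(k - 1) * 2 + 1:2, (k - 1) * 2 + 1:2] <- NA
  expect_equal(sum(off == 0, na.rm = TRUE), 80L)  # 40 distinct cross parameters
  for (k in 1:5) {
    ix <- (k - 1) * 2 + 1:2
    expect_equal(sep$D[ix, ix], comp$D[ix, ix])
  }
  # idempotence
  sep2 <- separate_components(sep)
  expect_equal(sep2$D, sep$D)
  expect_equal(sep2$R, sep$R)
  # separated working model must have zero cross entries
  expect_error(working_model("separated", comp), "zero cross-measure")
  expect_s3_class(working_model("separated", sep), "working_model")
})
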