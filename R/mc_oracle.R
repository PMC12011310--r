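# symmetric square root of a PSD matrix, clamping tiny negative eigenvalues
cov_sqrt <- function(M) {
  e <- eigen((M + t(M)) / 2, symmetric = TRUE)
  if (min(e$values) < -1e-8 * max(1, max(abs(e$values))))
    stop("covariance matrix is not positive semi-definite")
  e$vectors %*% (sqrt(pmax(e$values, 0)) * t(e$vectors))
}

#' Simulate one subject from the true joint model
#'
#' Draws `b_i ~ N(0, D)`, `e_i ~ N(0, Sigma_i)` and returns
#' `Y_i = X_i beta + Z_i b_i + e_i` together with the latent draws.
#' Reproducible given the RNG state (set a seed before calling, or pass one).
#'
#' @param subject a `subject_design`.
#' @param components true `covariance_components`.
#' @param beta fixed-effects vector (defaults to zero).
#' @param seed optional integer; when given, the draw uses a temporary RNG
#'   state and leaves the caller's stream untouched.
#' @return list with `Y`, `b`, `e`.
#' @export
simulate_subject <- function(subject, components, beta = NULL, seed = NULL) {
  des <- assemble_block_design(subject)
  if (is.null(beta)) beta <- numeric(ncol(des$X))
  Dh <- cov_sqrt(components$D)
  Sh <- cov_sqrt(build_residual_cov(subject, components$R))
  draw <- function() {
    b <- as.numeric(Dh %*% rnorm(nrow(Dh)))
    e <- as.numeric(Sh %*% rnorm(nrow(Sh)))
    list(Y = as.numeric(des$X %*% beta + des$Z %*% b + e), b = b, e = e)
  }
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

#' Monte-Carlo estimate of a working-model estimator's MSE
#'
#' Simulates repeatedly from the true joint model, applies the working-model
#' estimator (the same linear maps the closed forms describe), and estimates
#' the empirical MSE with a Monte-Carlo standard error. For random effects
#' and predictions the squared bias (the average squared conditional bias
#' given the random effects) is estimated without reference to the closed
#' forms by drawing two independent error vectors per random-effect draw:
#' the cross-product of the two resulting estimation errors is unbiased for
#' the squared conditional bias. For fixed effects the estimator is
#' unconditionally unbiased and the empirical squared bias is the
#' variance-debiased squared mean error.
#'
#' @param subjects list of `subject_design` (or one).
#' @param true_components true `covariance_components`.
#' @param working `"combined"`, `"separated"`, or a `working_model`.
#' @param estimand `"beta"`, `"b"` or `"y"`.
#' @param beta_known logical; ignored for `estimand = "beta"`.
#' @param n_reps number of Monte-Carlo replicates (>= 1000).
#' @param seed integer seed.
#' @param chunk_size replicates simulated per block (memory control).
#' @return object of class `oracle_report`: `empirical` and `se` lists with
#'   `mse`, `bias2`, `var`; the matching `closed_form` decomposition; and
#'   `z`, the standardized empirical-minus-closed-form discrepancies.
#' @export
empirical_mse <- function(subjects, true_components, working,
                          estimand = c("b", "beta", "y"), beta_known = TRUE,
                          n_reps = 1e5, seed = 1L, chunk_size = 10000L) {
  estimand <- match.arg(estimand)
  if (inherits(subjects, "subject_design")) subjects <- list(subjects)
  stopifnot(n_reps >= 1000)
  use_beta_hat <- (estimand == "beta") || !beta_known

  if (use_beta_hat) {
    gm <- gls_map(subjects, true_components, working)
    ctx <- gm$ctx
    Astack <- do.call(cbind, gm$A)
  } else {
    ctx <- prepare_context(subjects, true_components, working)
  }
  m <- length(ctx)
  n_i <- vapply(ctx, function(c) nrow(c$Z), integer(1))
  q_tot <- ncol(ctx[[1]]$Z)
  ridx <- split(seq_len(sum(n_i)), rep(seq_len(m), n_i))
  bidx <- split(seq_len(m * q_tot), rep(seq_len(m), each = q_tot))
  Zbig <- as.matrix(Matrix::bdiag(lapply(ctx, `[[`, "Z")))
  Dh <- cov_sqrt(true_components$D)
  Sh <- lapply(ctx, function(c) cov_sqrt(c$Sigma_t))

  closed <- switch(estimand,
    beta = fixed_effects_mse(subjects, true_components, working),
    b = random_effects_mse(subjects, true_components, working, beta_known),
    y = predicted_values_mse(subjects, true_components, working, beta_known))

  stat_mse <- numeric(n_reps)
  stat_bias <- numeric(n_reps)       # per-rep cross-product (b/y) only
  p <- if (use_beta_hat) nrow(gm$G_inv) else 0L
  err_sum <- numeric(p); err_sumsq <- numeric(p)

  transform_E <- function(Eraw) {
    for (i in seq_len(m))
      Eraw[, ridx[[i]]] <- Eraw[, ridx[[i]], drop = FALSE] %*% t(Sh[[i]])
    Eraw
  }
  errors_given <- function(Bt, Et, delta) {
    # returns (chunk x dim) matrix of estimation errors for the estimand
    Yc <- Bt %*% t(Zbig) + Et
    if (use_beta_hat) delta <- Yc %*% t(Astack)
    out <- NULL
    for (i in seq_len(m)) {
      resid_i <- Yc[, ridx[[i]], drop = FALSE]
      if (use_beta_hat && estimand != "beta")
        resid_i <- resid_i - delta %*% t(ctx[[i]]$X)
      if (estimand == "beta") { out <- delta; break }
      bhat <- resid_i %*% t(ctx[[i]]$L)
      err_b <- bhat - Bt[, bidx[[i]], drop = FALSE]
      piece <- if (estimand == "b") err_b
               else err_b %*% t(ctx[[i]]$Z) +
                    (if (use_beta_hat) delta %*% t(ctx[[i]]$X) else 0)
      out <- if (is.null(out)) piece else cbind(out, piece)
    }
    out
  }

  set.seed(seed)
  done <- 0L
  while (done < n_reps) {
    cs <- min(chunk_size, n_reps - done)
    Braw <- matrix(rnorm(cs * m * q_tot), cs)
    for (i in seq_len(m))
      Braw[, bidx[[i]]] <- Braw[, bidx[[i]], drop = FALSE] %*% t(Dh)
    E1 <- transform_E(matrix(rnorm(cs * sum(n_i)), cs))
    err1 <- errors_given(Braw, E1, NULL)
    rows <- done + seq_len(cs)
    if (estimand == "beta") {
      stat_mse[rows] <- rowSums(err1^2)
      err_sum <- err_sum + colSums(err1)
      err_sumsq <- err_sumsq + colSums(err1^2)
    } else {
      E2 <- transform_E(matrix(rnorm(cs * sum(n_i)), cs))
      err2 <- errors_given(Braw, E2, NULL)
      stat_mse[rows] <- 0.5 * (rowSums(err1^2) + rowSums(err2^2))
      stat_bias[rows] <- rowSums(err1 * err2)
    }
    done <- done + cs
  }

  mse_emp <- mean(stat_mse)
  se_mse <- stats::sd(stat_mse) / sqrt(n_reps)
  if (estimand == "beta") {
    mu <- err_sum / n_reps
    s2 <- err_sumsq / n_reps - mu^2
    bias2_emp <- sum(mu^2 - s2 / n_reps)   # debiased squared mean error
    se_bias2 <- sqrt(2 * sum(s2^2)) / n_reps
    var_emp <- mse_emp - bias2_emp
    se_var <- se_mse
  } else {
    bias2_emp <- mean(stat_bias)
    se_bias2 <- stats::sd(stat_bias) / sqrt(n_reps)
    var_emp <- mse_emp - bias2_emp
    se_var <- stats::sd(stat_mse - stat_bias) / sqrt(n_reps)
  }
  z <- c(mse = (mse_emp - closed$mse) / se_mse,
         bias2 = (bias2_emp - closed$squared_bias) / max(se_bias2, 1e-300),
         var = (var_emp - closed$variance) / se_var)
  structure(list(empirical = list(mse = mse_emp, bias2 = bias2_emp,
                                  var = var_emp),
                 se = list(mse = se_mse, bias2 = se_bias2, var = se_var),
                 n_reps = n_reps, closed_form = closed, z = z,
                 estimand = estimand, seed = seed),
            class = "oracle_report")
}

#' @export
print.oracle_report <- function(x, ...) {
  cat(sprintf(
    "oracle report (%s, %d reps): empirical mse %.6g vs closed form %.6g (z = %.2f)\n",
    x$estimand, x$n_reps, x$empirical$mse, x$closed_form$mse, x$z[["mse"]]))
  invisible(x)
}

#' Random model configuration for closed-form validation
#'
#' Draws a small multivariate mixed-model configuration: per-measure random
#' intercept+slope designs at irregular times with optional missingness, a
#' random PSD random-effects covariance and a random PSD residual
#' cross-covariance with shared observation times across measures. Used to
#' validate the closed-form MSE decompositions against Monte-Carlo
#' estimates over a spread of K, designs and correlation strengths.
#'
#' @param seed integer seed.
#' @param K number of measures.
#' @param m number of subjects.
#' @param n_range range of per-measure observation counts.
#' @param p_extra extra fixed-effect columns beyond intercept and time.
#' @return list with `subjects`, `components`, `beta`.
#' @export
random_config <- function(seed, K = 2, m = 2, n_range = c(3, 7), p_extra = 1) {
  with_seed(seed, {
    q <- 2L
    subjects <- lapply(seq_len(m), function(i) {
      # distinct times only: duplicate within-measure times would break the
      # PSD guarantee of the shared-time residual rule
      base_times <- sort(sample(seq(0.25, 10, by = 0.25), max(n_range)))
      markers <- lapply(seq_len(K), function(k) {
        nk <- sample(seq(n_range[1], n_range[2]), 1)
        tk <- sort(sample(base_times, nk))   # shared-time pool across measures
        Z <- cbind(intercept = 1, slope = tk)
        X <- Z
        if (p_extra > 0)
          X <- cbind(X, matrix(stats::rnorm(nk * p_extra), nk,
                               dimnames = list(NULL, paste0("x", seq_len(p_extra)))))
        marker_design(paste0("m", k), tk, X, Z)
      })
      subject_design(paste0("s", i), markers)
    })
    A <- matrix(stats::rnorm((K * q)^2), K * q)
    D <- A %*% t(A) / (K * q) + 0.1 * diag(K * q)
    B <- matrix(stats::rnorm(K * K), K)
    R <- B %*% t(B) / K + 0.1 * diag(K)
    beta <- stats::rnorm(ncol(assemble_block_design(subjects[[1]])$X))
    list(subjects = subjects,
         components = covariance_components(D, R, q = rep(q, K)),
         beta = beta)
  })
}
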