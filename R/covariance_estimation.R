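#' Per-measure linear mixed model fit
#'
#' Fits one measure's univariate linear mixed model (random intercept and
#' slope per subject) by maximum likelihood with \pkg{lme4}, using the same
#' fixed-effects design block the cohort generator defines. This supplies
#' the within-measure variance components; cross-measure blocks come from
#' [cross_covariance_moments()].
#'
#' @param cohort an `mlmm_cohort` (from [simulate_cohort()] or assembled with
#'   [build_cohort_design()] plus the long data).
#' @param measure measure label to fit.
#' @return list with `beta_hat`, `D_kk` (2 x 2, intercept/slope), `sigma2`,
#'   `logLik`, `converged`, and the `lme4` fit in `fit`.
#' @export
fit_separated_lmm <- function(cohort, measure) {
  stopifnot(inherits(cohort, "mlmm_cohort") || is.list(cohort))
  meas_idx <- match(measure, vapply(cohort$subjects[[1]]$markers, `[[`,
                                    character(1), "measure_id"))
  if (is.na(meas_idx)) stop("unknown measure label: ", measure)
  if (length(cohort$subjects) < 2)
    stop("variance components are not identifiable from a single subject")
  Xs <- list(); dfs <- list()
  for (s in cohort$subjects) {
    mk <- s$markers[[meas_idx]]
    if (length(mk$times) == 0) next
    Xs[[length(Xs) + 1L]] <- mk$X
    dfs[[length(dfs) + 1L]] <- data.frame(subject_id = s$subject_id,
                                          time = mk$times,
                                          stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, dfs)
  dat <- cohort$data[cohort$data$measure == measure, ]
  key <- paste(df$subject_id, signif(df$time, 12))
  val <- stats::setNames(dat$value, paste(dat$subject_id, signif(dat$time, 12)))
  df$value <- as.numeric(val[key])
  df$X <- do.call(rbind, Xs)
  fit <- lme4::lmer(value ~ 0 + X + (1 + time | subject_id), data = df,
                    REML = FALSE,
                    control = lme4::lmerControl(check.conv.singular = "ignore"))
  vc <- lme4::VarCorr(fit)
  D_kk <- as.matrix(vc$subject_id)[1:2, 1:2]
  dimnames(D_kk) <- list(c("intercept", "slope"), c("intercept", "slope"))
  conv <- length(fit@optinfo$conv$lme4$messages) == 0
  list(beta_hat = unname(lme4::fixef(fit)), D_kk = D_kk,
       sigma2 = stats::sigma(fit)^2, logLik = as.numeric(stats::logLik(fit)),
       converged = conv, fit = fit)
}

# per-subject unshrunken effect estimates and conditional residuals for one
# measure: b* = (Z'Z)^{-1} Z'(y - X beta_hat), e_hat = (I - H)(y - X beta_hat)
unshrunken_effects <- function(cohort, meas_idx, beta_hat) {
  lapply(cohort$subjects, function(s) {
    mk <- s$markers[[meas_idx]]
    n <- length(mk$times)
    if (n < 2 || length(unique(mk$times)) < 2) return(NULL)
    dat <- cohort$data
    sel <- dat$subject_id == s$subject_id &
           dat$measure == mk$measure_id
    y <- dat$value[sel][order(dat$time[sel])]
    r <- y - as.numeric(mk$X %*% beta_hat)
    Z <- mk$Z
    P <- solve(crossprod(Z), t(Z))
    bstar <- as.numeric(P %*% r)
    list(bstar = bstar, ehat = r - as.numeric(Z %*% bstar),
         times = mk$times, P = P, Z = Z)
  })
}

#' Moment-based cross-measure covariance completion
#'
#' Combines per-measure mixed-model fits (within-measure blocks) with
#' method-of-moments estimates of the cross-measure blocks. For each subject
#' and measure, the unshrunken effect estimate
#' `b*_ik = (Z'Z)^{-1} Z' (y_ik - X_ik beta_hat_k)` is computed by ordinary
#' projection (no shrinkage, so cross-covariances are not attenuated). The
#' empirical cross-covariance of `(b*_ik, b*_ik')` is unbiased for `D_kk'`
#' up to a shared-time residual term `R_kk' * mean_i(P_ik S_i P_ik'')`,
#' which is estimated and subtracted; `R_kk'` itself is estimated from
#' products of conditional residuals at shared observation times, with an
#' exact finite-sample attenuation correction for the projection. The
#' assembled matrices are passed through [psd_repair()].
#'
#' @param cohort an `mlmm_cohort`.
#' @param fits named list of per-measure fits from [fit_separated_lmm()]
#'   (computed if missing).
#' @return object of class `component_estimates`: list with `components`
#'   (a `covariance_components` holding `D_hat`, `R_hat`), `beta_hat`,
#'   `fits`, and `n_pairs` (subjects contributing to each cross block).
#' @export
cross_covariance_moments <- function(cohort, fits = NULL) {
  measures <- vapply(cohort$subjects[[1]]$markers, `[[`, character(1),
                     "measure_id")
  K <- length(measures)
  if (is.null(fits)) {
    fits <- lapply(measures, function(k) fit_separated_lmm(cohort, k))
    names(fits) <- measures
  }
  eff <- lapply(seq_len(K), function(k)
    unshrunken_effects(cohort, k, fits[[k]]$beta_hat))
  q <- 2L
  D_hat <- matrix(0, K * q, K * q)
  lbl <- paste0(rep(measures, each = q), ":", c("intercept", "slope"))
  dimnames(D_hat) <- list(lbl, lbl)
  R_hat <- diag(vapply(fits, `[[`, numeric(1), "sigma2"), K)
  dimnames(R_hat) <- list(measures, measures)
  n_pairs <- matrix(0L, K, K, dimnames = list(measures, measures))
  for (k in seq_len(K)) {
    ix <- (k - 1) * q + seq_len(q)
    D_hat[ix, ix] <- fits[[k]]$D_kk
  }
  tie_tol <- 1e-9
  for (k in seq_len(K - 1)) for (l in (k + 1):K) {
    bk <- list(); bl <- list()
    r_num <- 0; r_den <- 0; psp_sum <- matrix(0, q, q); n_el <- 0L
    for (i in seq_along(cohort$subjects)) {
      ek <- eff[[k]][[i]]; el <- eff[[l]][[i]]
      if (is.null(ek) || is.null(el)) next
      n_el <- n_el + 1L
      bk[[n_el]] <- ek$bstar; bl[[n_el]] <- el$bstar
      S <- (abs(outer(ek$times, el$times, "-")) <= tie_tol) * 1
      if (any(S > 0)) {
        Hk <- ek$Z %*% ek$P; Hl <- el$Z %*% el$P
        att <- (diag(nrow(Hk)) - Hk) %*% S %*% t(diag(nrow(Hl)) - Hl)
        r_num <- r_num + sum((tcrossprod(ek$ehat, el$ehat))[S > 0])
        r_den <- r_den + sum(att[S > 0])
        psp_sum <- psp_sum + ek$P %*% S %*% t(el$P)
      }
    }
    if (n_el < 3) {
      warning("no eligible subjects for pair ", measures[k], "-", measures[l],
              "; cross block set to 0")
      next
    }
    r_kl <- if (abs(r_den) > 1e-12) r_num / r_den else 0
    Bk <- do.call(rbind, bk); Bl <- do.call(rbind, bl)
    cross <- crossprod(sweep(Bk, 2, colMeans(Bk)),
                       sweep(Bl, 2, colMeans(Bl))) / n_el -
             r_kl * psp_sum / n_el
    ixk <- (k - 1) * q + seq_len(q); ixl <- (l - 1) * q + seq_len(q)
    D_hat[ixk, ixl] <- cross; D_hat[ixl, ixk] <- t(cross)
    R_hat[k, l] <- R_hat[l, k] <- r_kl
    n_pairs[k, l] <- n_pairs[l, k] <- n_el
  }
  D_hat <- psd_repair(D_hat)
  R_hat <- psd_repair(R_hat)
  structure(list(components = covariance_components(D_hat, R_hat,
                                                    q = rep(q, K)),
                 beta_hat = lapply(fits, `[[`, "beta_hat"),
                 fits = fits, n_pairs = n_pairs),
            class = "component_estimates")
}

#' Estimate covariance components from a cohort
#'
#' Convenience wrapper: per-measure ML fits plus moment-based cross-measure
#' completion.
#'
#' @param cohort an `mlmm_cohort`.
#' @return a `component_estimates`.
#' @export
estimate_components <- function(cohort) cross_covariance_moments(cohort)

#' Empirical correlation of yearly biomarker averages
#'
#' Averages each subject's values per (measure, calendar year since onset)
#' and computes pairwise-complete correlations of the resulting
#' (measures x years) variables across subjects. Cells observed for fewer
#' than 3 subjects are dropped (their correlations set to `NA`).
#'
#' @param cohort an `mlmm_cohort` or a long data.frame with subject_id,
#'   measure, time, value.
#' @param years integer years to include.
#' @return correlation matrix of dimension `length(measures) * length(years)`
#'   with labels `"measure:year"`.
#' @export
empirical_yearly_correlation <- function(cohort, years = 0:10) {
  data <- if (inherits(cohort, "mlmm_cohort")) cohort$data else cohort
  measures <- if (inherits(cohort, "mlmm_cohort"))
    cohort$spec$measures else unique(data$measure)
  d <- data[floor(data$time) %in% years, ]
  d$year <- floor(d$time)
  key <- paste0(d$measure, ":", d$year)
  cell_mean <- tapply(d$value, list(d$subject_id, key), mean)
  cols <- as.vector(outer(years, measures, function(y, m) paste0(m, ":", y)))
  cols <- cols[cols %in% colnames(cell_mean)]
  M <- cell_mean[, cols, drop = FALSE]
  n_subj <- colSums(!is.na(M))
  M[, n_subj < 3] <- NA
  out <- suppressWarnings(stats::cor(M, use = "pairwise.complete.obs"))
  full <- matrix(NA_real_,
                 length(measures) * length(years), length(measures) * length(years))
  lbl <- as.vector(outer(years, measures, function(y, m) paste0(m, ":", y)))
  dimnames(full) <- list(lbl, lbl)
  full[rownames(out), colnames(out)] <- out
  dv <- diag(full)
  dv[!is.na(dv)] <- 1
  diag(full) <- dv
  full
}

#' Model-implied correlation of yearly values
#'
#' For random intercept+slope components, the implied covariance between a
#' single observation of measure k at year s and of measure l at year t is
#' `(1, s) D_kl (1, t)' + [s = t] R_kl`. Returned as a correlation matrix on
#' the same layout as [empirical_yearly_correlation()]. Separated components
#' yield exactly zero cross-measure entries.
#'
#' @param components a `covariance_components` with q = 2 per measure.
#' @param years integer years.
#' @param measures measure labels (defaults to `rownames(R)` or m1..mK).
#' @return correlation matrix with labels `"measure:year"`.
#' @export
implied_yearly_correlation <- function(components, years = 0:10,
                                       measures = NULL) {
  stopifnot(inherits(components, "covariance_components"),
            all(components$q == 2))
  K <- components$K
  if (is.null(measures)) {
    measures <- rownames(components$R)
    if (is.null(measures)) measures <- paste0("m", seq_len(K))
  }
  ny <- length(years)
  Zy <- cbind(1, years)
  V <- matrix(0, K * ny, K * ny)
  lbl <- as.vector(outer(years, measures, function(y, m) paste0(m, ":", y)))
  dimnames(V) <- list(lbl, lbl)
  for (k in seq_len(K)) for (l in seq_len(K)) {
    Dkl <- components$D[(k - 1) * 2 + 1:2, (l - 1) * 2 + 1:2]
    blk <- Zy %*% Dkl %*% t(Zy)
    if (!is.null(components$R)) blk <- blk + diag(ny) * components$R[k, l]
    V[(k - 1) * ny + seq_len(ny), (l - 1) * ny + seq_len(ny)] <- blk
  }
  stats::cov2cor(V)
}
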