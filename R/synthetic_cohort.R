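scleroderma_measures <- c("pFVC", "pDLCO", "EF", "RVSP", "mRSS")

#' Default covariance components of the five-marker synthetic cohort
#'
#' Random intercept and slope per measure (10 x 10 D) and a 5 x 5 residual
#' cross-covariance. The structure mimics the qualitative pattern seen in
#' scleroderma registries on the quantile-normalized scale: the two lung
#' measures strongly correlated, RVSP substantially correlated with both
#' lung measures and skin, and EF uncorrelated with everything. Intercept
#' variance is 1 and slope variance 0.005 per measure (time in years over a
#' 0-40 horizon), with a -0.2 intercept-slope correlation; the
#' between-measure correlation applies to intercepts and slopes alike via a
#' Kronecker construction, which keeps the matrix positive definite.
#'
#' @return a `covariance_components` with 2 random effects per measure,
#'   dimnames `"measure:effect"`.
#' @export
scleroderma_components <- function() {
  meas <- scleroderma_measures
  C <- diag(5); dimnames(C) <- list(meas, meas)
  set_c <- function(M, a, b, v) { M[a, b] <- v; M[b, a] <- v; M }
  C <- set_c(C, "pFVC", "pDLCO", 0.8)
  C <- set_c(C, "pFVC", "RVSP", 0.55)
  C <- set_c(C, "pDLCO", "RVSP", 0.6)
  C <- set_c(C, "pFVC", "mRSS", 0.35)
  C <- set_c(C, "pDLCO", "mRSS", 0.35)
  C <- set_c(C, "RVSP", "mRSS", 0.5)
  C_eff <- matrix(c(1, -0.2, -0.2, 1), 2)
  sdv <- rep(c(1, sqrt(0.005)), 5)
  D <- kronecker(C, C_eff) * tcrossprod(sdv)
  lbl <- paste0(rep(meas, each = 2), ":", rep(c("intercept", "slope"), 5))
  dimnames(D) <- list(lbl, lbl)
  Rc <- diag(5); dimnames(Rc) <- list(meas, meas)
  Rc <- set_c(Rc, "pFVC", "pDLCO", 0.3)
  Rc <- set_c(Rc, "EF", "RVSP", 0.15)
  R <- Rc * 0.5   # residual variance 0.5 per measure
  covariance_components(D, R, q = rep(2L, 5))
}

#' Specification of a synthetic five-marker longitudinal cohort
#'
#' Defines the generator for scleroderma-like cohorts: five
#' quantile-normalized Gaussian measures observed at irregular visit times
#' over 0-40 years since disease onset, with the cardiac measures (EF, RVSP)
#' observed more sparsely than the pulmonary and skin measures. Default
#' per-measure visit-count targets are the registry summary intensities
#' (mean/sd): pFVC 12.83/6.20, pDLCO 12.40/6.01, EF 9.13/3.71, RVSP
#' 7.47/3.28, mRSS 19.09/7.61, truncated at `min_obs` to honour the
#' at-least-4-observations inclusion criterion.
#'
#' @param m number of subjects.
#' @param visit_mean,visit_sd named numeric vectors of per-measure target
#'   visit-count mean and standard deviation.
#' @param horizon follow-up horizon in years.
#' @param min_obs minimum observations per measure per subject.
#' @param components true `covariance_components` (defaults to
#'   [scleroderma_components()]).
#' @param beta named list of per-measure fixed-effect vectors, or `NULL` for
#'   the package defaults (mild spline-shaped decline, small covariate
#'   effects).
#' @param spline_df degrees of freedom of the natural spline of time.
#' @param seed integer seed.
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(m = 200,
                        visit_mean = c(pFVC = 12.83, pDLCO = 12.40, EF = 9.13,
                                       RVSP = 7.47, mRSS = 19.09),
                        visit_sd = c(pFVC = 6.20, pDLCO = 6.01, EF = 3.71,
                                     RVSP = 3.28, mRSS = 7.61),
                        horizon = 40, min_obs = 4,
                        components = scleroderma_components(),
                        beta = NULL, spline_df = 3, seed = 1L) {
  meas <- scleroderma_measures
  stopifnot(all(meas %in% names(visit_mean)), all(meas %in% names(visit_sd)),
            inherits(components, "covariance_components"),
            components$K == 5, min_obs >= 1)
  if (any(visit_mean[meas] < min_obs))
    stop("infeasible visit intensity: target mean below min_obs")
  structure(list(m = as.integer(m), measures = meas,
                 visit_mean = visit_mean[meas], visit_sd = visit_sd[meas],
                 horizon = horizon, min_obs = as.integer(min_obs),
                 components = components, beta = beta,
                 spline_df = as.integer(spline_df), seed = as.integer(seed)),
            class = "cohort_spec")
}

# negative-binomial (size, mu) whose min_obs-truncated distribution matches a
# target mean/sd; falls back to a truncated Poisson when the target is
# underdispersed
match_count_dist <- function(mean, sd, min_obs, max_x = 1000) {
  xs <- min_obs:max_x
  tm <- function(p) {
    p <- p / sum(p)
    m1 <- sum(xs * p)
    c(m1, sqrt(sum(xs^2 * p) - m1^2))
  }
  if (sd^2 > mean) {
    obj <- function(par) {
      mo <- tm(stats::dnbinom(xs, size = exp(par[1]), mu = exp(par[2])))
      (mo[1] - mean)^2 + (mo[2] - sd)^2
    }
    size0 <- mean^2 / max(sd^2 - mean, 1e-6)
    fit <- stats::optim(log(c(size0, mean)), obj)
    list(family = "nbinom", size = exp(fit$par[1]), mu = exp(fit$par[2]))
  } else {
    obj <- function(par) {
      mo <- tm(stats::dpois(xs, lambda = exp(par)))
      (mo[1] - mean)^2
    }
    fit <- stats::optimize(obj, interval = log(c(max(mean - 3 * sd, 0.5), mean + 3 * sd + 1)))
    list(family = "pois", lambda = exp(fit$minimum))
  }
}

sample_counts <- function(dist, n, min_obs) {
  draw <- function(k) {
    if (dist$family == "nbinom") stats::rnbinom(k, size = dist$size, mu = dist$mu)
    else stats::rpois(k, lambda = dist$lambda)
  }
  x <- draw(n)
  while (any(bad <- x < min_obs)) x[bad] <- draw(sum(bad))
  x
}

#' Sample per-subject, per-measure visit times
#'
#' Visit counts are drawn per measure from a negative-binomial calibrated so
#' that its `min_obs`-truncated mean and sd match the spec targets (a
#' degenerate sd of 0 gives every subject the same count). Times come from a
#' shared clinic-day process per subject (uniform order statistics over the
#' horizon): the two pulmonary measures are drawn from a common
#' pulmonary-test day subset, the two cardiac measures from a common
#' echocardiogram day subset, and mRSS directly from clinic days. This
#' guarantees exactly shared observation times within and across measure
#' groups, so cross-measure residual correlation is realized in the data.
#'
#' @param spec a `cohort_spec`.
#' @return list of length `m`; each element a named list of sorted time
#'   vectors per measure.
#' @export
sample_visit_process <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  meas <- spec$measures
  counts <- matrix(0L, spec$m, 5, dimnames = list(NULL, meas))
  for (k in meas) {
    if (spec$visit_sd[k] == 0) {
      counts[, k] <- max(round(spec$visit_mean[k]), spec$min_obs)
    } else {
      dist <- match_count_dist(spec$visit_mean[k], spec$visit_sd[k], spec$min_obs)
      counts[, k] <- sample_counts(dist, spec$m, spec$min_obs)
    }
  }
  lapply(seq_len(spec$m), function(i) {
    ci <- counts[i, ]
    n_clinic <- max(ci)
    clinic <- sort(stats::runif(n_clinic, 0, spec$horizon))
    pulm <- sort(sample(clinic, max(ci["pFVC"], ci["pDLCO"])))
    echo <- sort(sample(clinic, max(ci["EF"], ci["RVSP"])))
    list(pFVC = sort(sample(pulm, ci["pFVC"])),
         pDLCO = sort(sample(pulm, ci["pDLCO"])),
         EF = sort(sample(echo, ci["EF"])),
         RVSP = sort(sample(echo, ci["RVSP"])),
         mRSS = sort(sample(clinic, ci["mRSS"])))
  })
}

sample_covariates <- function(m) {
  data.frame(
    subject_id = paste0("s", seq_len(m)),
    age_onset = round(stats::rnorm(m, 45, 12), 1),
    female = stats::rbinom(m, 1, 0.85),
    nonwhite = stats::rbinom(m, 1, 0.30),
    diffuse_skin = stats::rbinom(m, 1, 0.40),
    aca = stats::rbinom(m, 1, 0.35),
    scl70 = stats::rbinom(m, 1, 0.25),
    rnapol3 = stats::rbinom(m, 1, 0.15),
    stringsAsFactors = FALSE)
}

covariate_columns <- function(covariates) {
  cbind(age_onset_c = (covariates$age_onset - 45) / 10,
        female = covariates$female, nonwhite = covariates$nonwhite,
        diffuse_skin = covariates$diffuse_skin, aca = covariates$aca,
        scl70 = covariates$scl70, rnapol3 = covariates$rnapol3)
}

# fixed-effects design row block: [1, NS(t), covs, covs x NS(t)]
fixed_design_block <- function(times, cov_row, knots, boundary) {
  ns_mat <- splines::ns(times, knots = knots, Boundary.knots = boundary)
  colnames(ns_mat) <- paste0("ns", seq_len(ncol(ns_mat)))
  base <- cbind(intercept = 1, ns_mat)
  cov_mat <- matrix(cov_row, nrow = length(times), ncol = length(cov_row),
                    byrow = TRUE, dimnames = list(NULL, names(cov_row)))
  inter <- do.call(cbind, lapply(seq_along(cov_row), function(j) {
    mj <- ns_mat * cov_row[j]
    colnames(mj) <- paste0(names(cov_row)[j], ":", colnames(ns_mat))
    mj
  }))
  cbind(base, cov_mat, inter)
}

default_beta <- function(spec, p) {
  # mild measure-specific decline over the spline terms, small covariate and
  # interaction effects; exact values are immaterial to efficiency ratios
  lapply(stats::setNames(seq_along(spec$measures), spec$measures), function(k) {
    b <- numeric(p)
    b[1] <- 0.2 * (k - 3)
    b[2:(1 + spec$spline_df)] <- -0.3 * seq_len(spec$spline_df) / k
    b[(2 + spec$spline_df):p] <- 0.05
    b
  })
}

#' Spline knots used by the cohort designs
#'
#' Interior knots at the 33rd/66th percentiles of the pooled observation
#' times, boundary knots at 0 and the horizon.
#' @param times pooled numeric times.
#' @param horizon study horizon.
#' @return list with `knots` and `boundary`.
#' @export
cohort_knots <- function(times, horizon = 40) {
  list(knots = as.numeric(stats::quantile(times, c(1, 2) / 3)),
       boundary = c(0, horizon))
}

#' Simulate a synthetic five-marker cohort
#'
#' Draws visit processes, baseline covariates, random effects
#' `b_i ~ N(0, D)` and residuals with shared-time cross-measure correlation,
#' and returns the long-format table plus the per-subject designs and latent
#' truth. The fixed-effects design of every measure uses identical column
#' definitions: intercept, natural spline of time (3 df by default), the
#' baseline covariates, and covariate-by-spline interactions.
#'
#' @param spec a `cohort_spec`.
#' @return object of class `mlmm_cohort`: list with `data` (long data.frame:
#'   subject_id, measure, time, value), `covariates`, `subjects` (list of
#'   `subject_design`), `truth` (components, beta, random effects), `knots`,
#'   and the `spec`.
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  visits <- sample_visit_process(spec)
  covariates <- sample_covariates(spec$m)
  pooled <- unlist(visits, use.names = FALSE)
  kn <- cohort_knots(pooled, spec$horizon)
  cov_cols <- covariate_columns(covariates)
  p <- 1 + spec$spline_df + ncol(cov_cols) * (1 + spec$spline_df)
  beta <- spec$beta
  if (is.null(beta)) beta <- default_beta(spec, p)
  stopifnot(all(lengths(beta) == p))
  beta_stacked <- unlist(beta[spec$measures], use.names = FALSE)

  subjects <- vector("list", spec$m)
  b_true <- matrix(NA_real_, spec$m, nrow(spec$components$D),
                   dimnames = list(covariates$subject_id,
                                   rownames(spec$components$D)))
  rows <- vector("list", spec$m)
  for (i in seq_len(spec$m)) {
    markers <- lapply(spec$measures, function(k) {
      tk <- visits[[i]][[k]]
      marker_design(k, tk,
                    X = fixed_design_block(tk, cov_cols[i, ], kn$knots, kn$boundary),
                    Z = cbind(intercept = 1, slope = tk), check_rank = FALSE)
    })
    s <- subject_design(covariates$subject_id[i], markers)
    subjects[[i]] <- s
    sim <- simulate_subject(s, spec$components, beta_stacked)
    b_true[i, ] <- sim$b
    rows[[i]] <- data.frame(
      subject_id = covariates$subject_id[i],
      measure = rep(spec$measures, s$n_ik),
      time = unlist(lapply(s$markers, `[[`, "times"), use.names = FALSE),
      value = sim$Y, stringsAsFactors = FALSE)
  }
  structure(list(data = do.call(rbind, rows), covariates = covariates,
                 subjects = subjects,
                 truth = list(components = spec$components, beta = beta,
                              b = b_true),
                 knots = kn, spec = spec),
            class = "mlmm_cohort")
}

#' Rebuild subject designs from a long cohort table
#'
#' Constructs the per-subject, per-measure design blocks (natural spline of
#' time, baseline covariates and their spline interactions as fixed effects;
#' intercept and time as random effects) from a long-format table and a
#' baseline covariate table. Useful when the cohort was read from CSV rather
#' than generated by [simulate_cohort()].
#'
#' @param data long data.frame with columns subject_id, measure, time (and
#'   optionally value).
#' @param covariates data.frame with subject_id plus the baseline covariates.
#' @param measures measure order (defaults to the five-marker panel).
#' @param spline_df spline degrees of freedom.
#' @param horizon study horizon in years.
#' @return list with `subjects` and `knots`.
#' @export
build_cohort_design <- function(data, covariates,
                                measures = scleroderma_measures,
                                spline_df = 3, horizon = 40) {
  stopifnot(all(c("subject_id", "measure", "time") %in% names(data)),
            all(data$measure %in% measures))
  kn <- cohort_knots(data$time, horizon)
  cov_cols <- covariate_columns(covariates)
  ids <- covariates$subject_id
  subjects <- lapply(seq_along(ids), function(i) {
    di <- data[data$subject_id == ids[i], , drop = FALSE]
    markers <- lapply(measures, function(k) {
      tk <- sort(di$time[di$measure == k])
      marker_design(k, tk,
                    X = fixed_design_block(tk, cov_cols[i, ], kn$knots, kn$boundary),
                    Z = cbind(intercept = 1, slope = tk), check_rank = FALSE)
    })
    subject_design(ids[i], markers)
  })
  list(subjects = subjects, knots = kn)
}

#' Rank-based inverse normal (quantile) transform
#'
#' Maps values to `qnorm(rank / (n + 1))` with average ranks for ties, so the
#' output is strictly rank-preserving with an approximately standard Gaussian
#' marginal.
#'
#' @param x numeric vector with at least 2 distinct values.
#' @return transformed numeric vector.
#' @export
quantile_normalize <- function(x) {
  x <- as.numeric(x)
  if (length(unique(x[!is.na(x)])) < 2) stop("constant input")
  r <- rank(x, ties.method = "average", na.last = "keep")
  stats::qnorm(r / (sum(!is.na(x)) + 1))
}

#' Orient measures so that larger values mean better status
#'
#' Multiplies the listed measures' values by -1 (by convention RVSP and
#' mRSS, where higher raw values indicate worse disease). Applying the
#' transform twice restores the input.
#'
#' @param data long data.frame with columns `measure` and `value`.
#' @param flip measures to negate.
#' @return the data.frame with flipped values.
#' @export
orient_measures <- function(data, flip = c("RVSP", "mRSS")) {
  stopifnot(all(c("measure", "value") %in% names(data)))
  unknown <- setdiff(flip, unique(data$measure))
  if (length(unknown)) stop("unknown measure label: ", paste(unknown, collapse = ", "))
  sel <- data$measure %in% flip
  data$value[sel] <- -data$value[sel]
  data
}
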