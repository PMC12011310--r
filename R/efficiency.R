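#' MSE decomposition of a linear estimator under the true model
#'
#' Container for the exact mean squared error of a working-model estimator
#' evaluated under the true joint model, split into squared bias and
#' variance. `mse = squared_bias + variance` and `mse = sum(per_coordinate)`
#' hold by construction and are validated.
#'
#' @param per_coordinate_bias2 named vector of per-coordinate squared bias.
#' @param per_coordinate_var named vector of per-coordinate variance.
#' @param per_subject optional matrix (subjects x coordinates) of per-subject
#'   per-coordinate MSE contributions; used for mean-of-ratios summaries.
#' @return object of class `mse_decomposition` with fields `mse`,
#'   `squared_bias`, `variance`, `per_coordinate`, `coordinate_labels`.
#' @export
mse_decomposition <- function(per_coordinate_bias2, per_coordinate_var,
                              per_subject = NULL) {
  stopifnot(length(per_coordinate_bias2) == length(per_coordinate_var))
  per_coordinate <- per_coordinate_bias2 + per_coordinate_var
  out <- structure(
    list(mse = sum(per_coordinate),
         squared_bias = sum(per_coordinate_bias2),
         variance = sum(per_coordinate_var),
         per_coordinate = per_coordinate,
         per_coordinate_bias2 = per_coordinate_bias2,
         per_coordinate_var = per_coordinate_var,
         coordinate_labels = names(per_coordinate),
         per_subject = per_subject),
    class = "mse_decomposition")
  rel <- max(1, abs(out$mse))
  stopifnot(abs(out$mse - out$squared_bias - out$variance) <= 1e-10 * rel,
            abs(out$mse - sum(out$per_coordinate)) <= 1e-10 * rel)
  out
}

#' @export
print.mse_decomposition <- function(x, ...) {
  cat(sprintf("MSE decomposition: mse = %.6g (bias^2 = %.6g, variance = %.6g)\n",
              x$mse, x$squared_bias, x$variance))
  invisible(x)
}

#' Working-model covariance components from the truth
#'
#' The combined working model uses the true components; the separated working
#' model uses them with every cross-measure block zeroed.
#'
#' @param true_components a `covariance_components`.
#' @param label `"combined"` or `"separated"`.
#' @return a `working_model`.
#' @export
working_from_truth <- function(true_components, label = c("combined", "separated")) {
  label <- match.arg(label)
  comp <- if (label == "separated") separate_components(true_components)
          else true_components
  working_model(label, comp)
}

# Precompute per-subject design and covariance pieces for one working model
# evaluated under the truth. `subjects` is a list of subject_design.
prepare_context <- function(subjects, true_components, working) {
  if (inherits(subjects, "subject_design")) subjects <- list(subjects)
  if (is.character(working)) working <- working_from_truth(true_components, working)
  stopifnot(inherits(working, "working_model"))
  wc <- working$components
  lapply(subjects, function(s) {
    des <- assemble_block_design(s)
    Sig_t <- build_residual_cov(s, true_components$R)
    Sig_w <- build_residual_cov(s, wc$R)
    mc_w <- marginal_cov(s, wc, Z = des$Z, Sigma = Sig_w)
    L <- wc$D %*% crossprod(des$Z, mc_w$W)     # BLUP map D_w Z' V_w^{-1}
    V_t <- des$Z %*% true_components$D %*% t(des$Z) + Sig_t
    if (is.null(colnames(des$X)))
      colnames(des$X) <- paste0("beta", seq_len(ncol(des$X)))
    list(subject = s, X = des$X, Z = des$Z, W = mc_w$W, L = L,
         Sigma_t = Sig_t, V_t = (V_t + t(V_t)) / 2)
  })
}

# coordinate labels "measure:effect" for the stacked random effects
re_labels <- function(subject, q) {
  unlist(Map(function(m, qk) {
    eff <- colnames(m$Z)
    if (is.null(eff)) eff <- paste0("re", seq_len(qk))
    paste0(m$measure_id, ":", eff)
  }, subject$markers, q))
}

tr_quad <- function(C, M) sum((C %*% M) * C)        # trace(C M C')
diag_quad <- function(C, M) rowSums((C %*% M) * C)  # diag(C M C')

#' GLS coefficient-estimator map of a working model
#'
#' The fixed effects of either working model are generalized least squares
#' estimates with weights from that model's marginal covariance:
#' `beta_hat = G^{-1} sum_i X_i' W_i Y_i` with `G = sum_i X_i' W_i X_i`.
#' Returns the per-subject linear maps `A_i = G^{-1} X_i' W_i`, which satisfy
#' `sum_i A_i X_i = I` (unbiasedness under any mean-correct model).
#'
#' @param subjects list of `subject_design` (or a single one).
#' @param true_components a `covariance_components` describing the truth.
#' @param working `"combined"`, `"separated"`, or a `working_model`.
#' @return list with `A` (per-subject maps), `G_inv`, and the prepared
#'   per-subject context in `ctx`.
#' @export
gls_map <- function(subjects, true_components, working) {
  ctx <- prepare_context(subjects, true_components, working)
  p <- ncol(ctx[[1]]$X)
  G <- matrix(0, p, p)
  XtW <- lapply(ctx, function(ci) {
    xw <- crossprod(ci$X, ci$W)
    G <<- G + xw %*% ci$X
    xw
  })
  G <- (G + t(G)) / 2
  ch <- tryCatch(chol(G), error = function(e) NULL)
  if (is.null(ch)) stop("fixed effects not identifiable")
  G_inv <- chol2inv(ch)
  A <- lapply(XtW, function(xw) G_inv %*% xw)
  list(A = A, G_inv = G_inv, ctx = ctx,
       labels = colnames(ctx[[1]]$X))
}

#' Exact MSE of working-model fixed effects under the true model
#'
#' Both working models yield unbiased GLS estimators, so the squared bias is
#' exactly zero and the MSE equals the trace of
#' `sum_i A_i V_true,i A_i'`, the covariance of `beta_hat` under the truth.
#'
#' @inheritParams gls_map
#' @return an `mse_decomposition` with coordinates labelled by coefficient.
#' @export
fixed_effects_mse <- function(subjects, true_components, working) {
  gm <- gls_map(subjects, true_components, working)
  p <- length(gm$labels)
  v <- numeric(p)
  for (i in seq_along(gm$A)) v <- v + diag_quad(gm$A[[i]], gm$ctx[[i]]$V_t)
  names(v) <- gm$labels
  b2 <- numeric(p); names(b2) <- gm$labels
  mse_decomposition(b2, v)
}

#' BLUP linear map of a working model
#'
#' Returns `L_i = D_w Z_i' V_w,i^{-1}`, the map taking centred data
#' `Y_i - X_i beta` (known beta) or `Y_i - X_i beta_hat_w` (estimated beta)
#' to the working-model random-effect estimates.
#'
#' @param subject a `subject_design`.
#' @inheritParams gls_map
#' @return matrix of dimension (sum q_k) x n_i.
#' @export
blup_map <- function(subject, true_components, working) {
  ctx <- prepare_context(list(subject), true_components, working)
  ctx[[1]]$L
}

#' Exact MSE of working-model random-effect estimates under the true model
#'
#' With known beta the error of the BLUP-type estimator is
#' `(L_i Z_i - I) b_i + L_i e_i` with `b_i` independent of `e_i`, so the
#' average conditional MSE over the random-effects distribution decomposes as
#' squared bias `tr[(L_i Z_i - I) D_true (L_i Z_i - I)']` plus variance
#' `tr[L_i Sigma_true,i L_i']`. With estimated beta the error additionally
#' carries `-L_i X_i (beta_hat - beta)` where
#' `beta_hat - beta = sum_j A_j (Z_j b_j + e_j)` couples all subjects; the
#' MSE is the trace of the covariance of the full linear map under the truth,
#' accumulated exactly over subjects.
#'
#' @param subjects list of `subject_design` (or a single one).
#' @inheritParams gls_map
#' @param beta_known logical; if `FALSE`, accounts for the sampling error of
#'   the shared GLS fixed-effects estimate.
#' @return an `mse_decomposition`; coordinates are the stacked random effects
#'   labelled `"measure:effect"`, summed over subjects, with the per-subject
#'   contributions available in `per_subject`.
#' @export
random_effects_mse <- function(subjects, true_components, working,
                               beta_known = TRUE) {
  if (inherits(subjects, "subject_design")) subjects <- list(subjects)
  D_t <- true_components$D
  labels <- re_labels(subjects[[1]], true_components$q)
  nq <- length(labels)
  b2 <- v <- numeric(nq)
  per_subj <- matrix(0, length(subjects), nq,
                     dimnames = list(NULL, labels))
  if (beta_known) {
    ctx <- prepare_context(subjects, true_components, working)
    for (i in seq_along(ctx)) {
      ci <- ctx[[i]]
      Cb <- ci$L %*% ci$Z; diag(Cb) <- diag(Cb) - 1
      b2i <- diag_quad(Cb, D_t)
      vi <- diag_quad(ci$L, ci$Sigma_t)
      b2 <- b2 + b2i; v <- v + vi
      per_subj[i, ] <- b2i + vi
    }
  } else {
    gm <- gls_map(subjects, true_components, working)
    ctx <- gm$ctx
    p <- length(gm$labels)
    # pooled contributions of beta_hat sampling error under the truth
    S_b <- matrix(0, p, p)   # sum_j (A_j Z_j) D (A_j Z_j)'
    S_e <- matrix(0, p, p)   # sum_j A_j Sigma_t,j A_j'
    AZ <- vector("list", length(ctx))
    for (j in seq_along(ctx)) {
      AZ[[j]] <- gm$A[[j]] %*% ctx[[j]]$Z
      S_b <- S_b + AZ[[j]] %*% D_t %*% t(AZ[[j]])
      S_e <- S_e + gm$A[[j]] %*% ctx[[j]]$Sigma_t %*% t(gm$A[[j]])
    }
    for (i in seq_along(ctx)) {
      ci <- ctx[[i]]
      Fi <- ci$L %*% ci$X
      Cb_ii <- ci$L %*% ci$Z - Fi %*% AZ[[i]]; diag(Cb_ii) <- diag(Cb_ii) - 1
      Ce_ii <- ci$L - Fi %*% gm$A[[i]]
      Sb_not_i <- S_b - AZ[[i]] %*% D_t %*% t(AZ[[i]])
      Se_not_i <- S_e - gm$A[[i]] %*% ci$Sigma_t %*% t(gm$A[[i]])
      b2i <- diag_quad(Cb_ii, D_t) + diag_quad(Fi, Sb_not_i)
      vi <- diag_quad(Ce_ii, ci$Sigma_t) + diag_quad(Fi, Se_not_i)
      b2 <- b2 + b2i; v <- v + vi
      per_subj[i, ] <- b2i + vi
    }
  }
  names(b2) <- names(v) <- labels
  mse_decomposition(b2, v, per_subject = per_subj)
}

#' Exact MSE of working-model predicted trajectories under the true model
#'
#' The estimand is the subject's conditional mean trajectory
#' `E(y_i | b_i) = X_i beta + Z_i b_i`; the estimator is
#' `yhat_i = X_i beta_hat_w + Z_i bhat_w,i` (with `beta_hat_w = beta` when
#' `beta_known`). Coordinates are aggregated per measure (observation rows
#' grouped by measure, then summed over subjects).
#'
#' @inheritParams random_effects_mse
#' @return an `mse_decomposition` with one coordinate per measure.
#' @export
predicted_values_mse <- function(subjects, true_components, working,
                                 beta_known = TRUE) {
  if (inherits(subjects, "subject_design")) subjects <- list(subjects)
  D_t <- true_components$D
  measures <- vapply(subjects[[1]]$markers, `[[`, character(1), "measure_id")
  K <- length(measures)
  b2 <- v <- structure(numeric(K), names = measures)
  per_subj <- matrix(0, length(subjects), K, dimnames = list(NULL, measures))
  sum_by_measure <- function(x, s) {
    grp <- rep(seq_len(K), s$n_ik)
    vapply(seq_len(K), function(k) sum(x[grp == k]), numeric(1))
  }
  if (!beta_known) {
    gm <- gls_map(subjects, true_components, working)
    ctx <- gm$ctx
    p <- length(gm$labels)
    S_b <- matrix(0, p, p); S_e <- matrix(0, p, p)
    AZ <- vector("list", length(ctx))
    for (j in seq_along(ctx)) {
      AZ[[j]] <- gm$A[[j]] %*% ctx[[j]]$Z
      S_b <- S_b + AZ[[j]] %*% D_t %*% t(AZ[[j]])
      S_e <- S_e + gm$A[[j]] %*% ctx[[j]]$Sigma_t %*% t(gm$A[[j]])
    }
  } else {
    ctx <- prepare_context(subjects, true_components, working)
  }
  for (i in seq_along(ctx)) {
    ci <- ctx[[i]]
    ZL <- ci$Z %*% ci$L
    Cb0 <- ZL %*% ci$Z - ci$Z          # Z_i (L_i Z_i - I)
    if (beta_known) {
      b2i <- diag_quad(Cb0, D_t)
      vi <- diag_quad(ZL, ci$Sigma_t)
    } else {
      Gi <- ci$X - ZL %*% ci$X         # (I - Z_i L_i) X_i
      Cb_ii <- Cb0 + Gi %*% AZ[[i]]
      Ce_ii <- ZL + Gi %*% gm$A[[i]]
      Sb_not_i <- S_b - AZ[[i]] %*% D_t %*% t(AZ[[i]])
      Se_not_i <- S_e - gm$A[[i]] %*% ci$Sigma_t %*% t(gm$A[[i]])
      b2i <- diag_quad(Cb_ii, D_t) + diag_quad(Gi, Sb_not_i)
      vi <- diag_quad(Ce_ii, ci$Sigma_t) + diag_quad(Gi, Se_not_i)
    }
    b2m <- sum_by_measure(b2i, ci$subject)
    vm <- sum_by_measure(vi, ci$subject)
    b2 <- b2 + b2m; v <- v + vm
    per_subj[i, ] <- b2m + vm
  }
  mse_decomposition(b2, v, per_subject = per_subj)
}

select_coords <- function(labels, select = "all", measure = NULL, effect = NULL) {
  keep <- rep(TRUE, length(labels))
  if (!identical(select, "all")) {
    if (is.character(select)) keep <- labels %in% select
    else stop("select must be 'all' or a character vector of labels")
  }
  parts <- strsplit(labels, ":", fixed = TRUE)
  if (!is.null(measure))
    keep <- keep & vapply(parts, `[[`, character(1), 1) %in% measure
  if (!is.null(effect))
    keep <- keep & vapply(parts, function(p) p[length(p)], character(1)) %in% effect
  if (!any(keep)) stop("empty coordinate selection")
  keep
}

#' MSE ratio of the combined to the separated working model
#'
#' Forms the ratio of summed per-coordinate MSEs over a coordinate selection,
#' numerator (conventionally the combined model) over denominator (the
#' separated model). Values below 1 quantify the efficiency loss of the
#' separated fit. Coordinates can be selected by explicit label, by measure,
#' or by effect (e.g. `effect = "intercept"` or `"slope"`). With
#' `method = "mean_of_ratios"` the per-subject ratios are averaged instead of
#' pooling the traces first.
#'
#' @param numerator,denominator `mse_decomposition` objects with matching
#'   coordinate labels.
#' @param select `"all"` or a character vector of coordinate labels.
#' @param measure,effect optional label filters applied on top of `select`.
#' @param method `"ratio_of_means"` (default; ratio of pooled traces) or
#'   `"mean_of_ratios"` (requires per-subject contributions).
#' @return scalar ratio.
#' @export
mse_ratio <- function(numerator, denominator, select = "all",
                      measure = NULL, effect = NULL,
                      method = c("ratio_of_means", "mean_of_ratios")) {
  method <- match.arg(method)
  stopifnot(inherits(numerator, "mse_decomposition"),
            inherits(denominator, "mse_decomposition"),
            identical(numerator$coordinate_labels, denominator$coordinate_labels))
  keep <- select_coords(numerator$coordinate_labels, select, measure, effect)
  if (method == "ratio_of_means") {
    den <- sum(denominator$per_coordinate[keep])
    if (den <= 0) stop("degenerate comparison")
    sum(numerator$per_coordinate[keep]) / den
  } else {
    if (is.null(numerator$per_subject) || is.null(denominator$per_subject))
      stop("mean_of_ratios requires per-subject contributions")
    num_s <- rowSums(numerator$per_subject[, keep, drop = FALSE])
    den_s <- rowSums(denominator$per_subject[, keep, drop = FALSE])
    if (any(den_s <= 0)) stop("degenerate comparison")
    mean(num_s / den_s)
  }
}

#' Tidy table of MSE decompositions for both working models
#'
#' Convenience wrapper producing one row per (estimand, working model) with
#' mse, squared bias and variance, for a fixed set of subjects.
#'
#' @inheritParams random_effects_mse
#' @param estimands subset of `c("beta", "b", "y")`.
#' @return data.frame.
#' @export
efficiency_table <- function(subjects, true_components, beta_known = TRUE,
                             estimands = c("beta", "b", "y")) {
  rows <- list()
  for (wlab in c("combined", "separated")) {
    if ("beta" %in% estimands) {
      d <- fixed_effects_mse(subjects, true_components, wlab)
      rows[[length(rows) + 1L]] <- data.frame(
        estimand = "beta", working_model = wlab, mse = d$mse,
        bias2 = d$squared_bias, var = d$variance)
    }
    if ("b" %in% estimands) {
      d <- random_effects_mse(subjects, true_components, wlab, beta_known)
      rows[[length(rows) + 1L]] <- data.frame(
        estimand = "b", working_model = wlab, mse = d$mse,
        bias2 = d$squared_bias, var = d$variance)
    }
    if ("y" %in% estimands) {
      d <- predicted_values_mse(subjects, true_components, wlab, beta_known)
      rows[[length(rows) + 1L]] <- data.frame(
        estimand = "y", working_model = wlab, mse = d$mse,
        bias2 = d$squared_bias, var = d$variance)
    }
  }
  do.call(rbind, rows)
}
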