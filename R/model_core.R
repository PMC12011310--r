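#' Per-measure design block
#'
#' A `marker_design` holds the observation times and the fixed- and
#' random-effects design blocks of one longitudinal measure for one subject.
#' In the multivariate linear mixed model each subject contributes one such
#' block per measure; the subject-level design matrices are their direct sums.
#'
#' @param measure_id character scalar naming the measure.
#' @param times numeric vector of observation times (any consistent study-time
#'   unit, e.g. years since disease onset or times scaled to \[-1, 1\]).
#' @param X fixed-effects design block, `length(times)` x `p_k`.
#' @param Z random-effects design block, `length(times)` x `q_k`.
#' @param check_rank validate full column rank of the blocks when there are
#'   enough rows. Disable for designs whose per-subject blocks are
#'   legitimately rank deficient (e.g. baseline covariates, constant within
#'   subject, interacted with time); identifiability of such models is
#'   enforced at the pooled GLS level instead.
#' @return An object of class `marker_design`.
#' @export
marker_design <- function(measure_id, times, X, Z, check_rank = TRUE) {
  X <- as.matrix(X)
  Z <- as.matrix(Z)
  n <- length(times)
  if (nrow(X) != n || nrow(Z) != n) {
    stop("row counts of X and Z must equal the number of observation times")
  }
  if (check_rank && n >= max(ncol(X), ncol(Z), 1L)) {
    if (n > 0 && qr(X)$rank < ncol(X)) stop("X is rank deficient")
    if (n > 0 && qr(Z)$rank < ncol(Z)) stop("Z is rank deficient")
  }
  structure(
    list(measure_id = as.character(measure_id), times = as.numeric(times),
         X = X, Z = Z),
    class = "marker_design"
  )
}

#' Subject-level design
#'
#' Stacks K `marker_design` blocks (one per measure, in a fixed measure order
#' shared by all subjects) into the subject-level design. Observations are
#' ordered measure by measure, time-ascending within measure; every block
#' index used elsewhere in the package derives from this single ordering.
#'
#' @param subject_id character scalar.
#' @param markers list of `marker_design`, one per measure, in measure order.
#' @return An object of class `subject_design` with element `n_i`, the total
#'   observation count.
#' @export
subject_design <- function(subject_id, markers) {
  if (length(markers) == 0) stop("no measures supplied")
  ok <- vapply(markers, inherits, logical(1), what = "marker_design")
  if (!all(ok)) stop("markers must be a list of marker_design objects")
  n_ik <- vapply(markers, function(m) length(m$times), integer(1))
  if (sum(n_ik) == 0) stop("no observations")
  structure(
    list(subject_id = as.character(subject_id), markers = markers,
         n_ik = n_ik, n_i = sum(n_ik)),
    class = "subject_design"
  )
}

#' Assemble block-diagonal subject design matrices
#'
#' Forms the subject-level matrices X_i and Z_i as direct (Kronecker) sums of
#' the per-measure blocks: measure 1 rows first, then measure 2, and so on.
#'
#' @param subject a `subject_design`.
#' @return list with dense matrices `X` (n_i x sum p_k) and `Z`
#'   (n_i x sum q_k).
#' @export
assemble_block_design <- function(subject) {
  stopifnot(inherits(subject, "subject_design"))
  if (subject$n_i == 0) stop("no observations")
  qualified <- function(M, id, stem) {
    nm <- colnames(M)
    if (is.null(nm)) nm <- paste0(stem, seq_len(ncol(M)))
    paste0(id, ":", nm)
  }
  Xs <- lapply(subject$markers, `[[`, "X")
  Zs <- lapply(subject$markers, `[[`, "Z")
  X <- as.matrix(Matrix::bdiag(Xs))
  Z <- as.matrix(Matrix::bdiag(Zs))
  colnames(X) <- unlist(Map(function(m, M) qualified(M, m$measure_id, "x"),
                            subject$markers, Xs))
  colnames(Z) <- unlist(Map(function(m, M) qualified(M, m$measure_id, "re"),
                            subject$markers, Zs))
  list(X = X, Z = Z)
}

#' Covariance components of a multivariate linear mixed model
#'
#' `D` is the random-effects covariance across all K measures (blocked by
#' measure: the rows/columns for measure k's q_k effects are contiguous).
#' `R` is the K x K cross-measure residual covariance per observation; its
#' diagonal gives each measure's error variance and its off-diagonal the
#' covariance of errors of two measures recorded at the same time.
#'
#' @param D symmetric positive semi-definite matrix (sum q_k square).
#' @param R symmetric positive semi-definite K x K matrix.
#' @param q integer vector of random-effect counts per measure (defaults to
#'   `rep(nrow(D)/nrow(R), nrow(R))`, i.e. equal q across measures).
#' @param tol eigenvalue tolerance for the PSD check.
#' @return An object of class `covariance_components`.
#' @export
covariance_components <- function(D, R, q = NULL, tol = 1e-10) {
  D <- as.matrix(D); R <- as.matrix(R)
  K <- nrow(R)
  if (is.null(q)) {
    if (nrow(D) %% K != 0) stop("cannot infer q: nrow(D) not a multiple of K")
    q <- rep(nrow(D) %/% K, K)
  }
  if (sum(q) != nrow(D)) stop("sum(q) must equal nrow(D)")
  check_symmetric(D, "D"); check_symmetric(R, "R")
  if (min(eigen(D, symmetric = TRUE, only.values = TRUE)$values) < -tol)
    stop("D is not positive semi-definite")
  if (min(eigen(R, symmetric = TRUE, only.values = TRUE)$values) < -tol)
    stop("R is not positive semi-definite")
  structure(list(D = D, R = R, q = as.integer(q), K = K),
            class = "covariance_components")
}

check_symmetric <- function(M, name, tol = 1e-8) {
  if (!is.matrix(M) || nrow(M) != ncol(M) ||
      max(abs(M - t(M))) > tol * max(1, max(abs(M)))) {
    stop(sprintf("%s must be a symmetric matrix", name))
  }
  invisible(TRUE)
}

# index of each measure's random-effect block within the stacked coordinates
block_index <- function(q) {
  ends <- cumsum(q)
  starts <- c(1L, head(ends, -1L) + 1L)
  Map(seq.int, starts, ends)
}

#' Project covariance components onto the separated working model
#'
#' Sets every cross-measure block of D and every off-diagonal entry of R to
#' exactly zero, leaving the within-measure blocks unchanged. The result is
#' the covariance structure implicitly assumed when each measure is modelled
#' by its own univariate linear mixed model. Idempotent.
#'
#' @param components a `covariance_components`.
#' @return `covariance_components` with block-diagonal D and diagonal R.
#' @export
separate_components <- function(components) {
  stopifnot(inherits(components, "covariance_components"))
  D <- components$D * 0
  idx <- block_index(components$q)
  for (b in idx) D[b, b] <- components$D[b, b]
  R <- diag(diag(components$R), nrow = components$K)
  dimnames(R) <- dimnames(components$R)
  covariance_components(D, R, q = components$q)
}

#' Working model label plus components
#'
#' @param label `"separated"` or `"combined"`.
#' @param components a `covariance_components`; for `"separated"` all
#'   cross-measure entries must already be exactly zero (use
#'   [separate_components()]).
#' @return An object of class `working_model`.
#' @export
working_model <- function(label = c("combined", "separated"), components) {
  label <- match.arg(label)
  stopifnot(inherits(components, "covariance_components"))
  if (label == "separated") {
    sep <- separate_components(components)
    if (max(abs(sep$D - components$D)) > 0 || max(abs(sep$R - components$R)) > 0)
      stop("separated working model must have zero cross-measure covariances")
  }
  structure(list(label = label, components = components),
            class = "working_model")
}

#' Eigenvalue-clipping PSD repair with diagonal preservation
#'
#' Projects a symmetric matrix onto the positive semi-definite cone by
#' spectral decomposition: eigenvalues below `floor` are raised to `floor`,
#' the matrix is reconstructed, and rows/columns are rescaled so the original
#' diagonal (the variances) is preserved exactly. This is the standard
#' clip-and-rescale repair used when a correlation grid produces an indefinite
#' covariance matrix. Already-PSD input is returned unchanged.
#'
#' @param M symmetric matrix.
#' @param floor smallest admissible eigenvalue (default 0; use a small
#'   positive value, e.g. 1e-8, when the result must later be inverted).
#' @return symmetric PSD matrix with `diag(result) == diag(M)`.
#' @export
psd_repair <- function(M, floor = 0) {
  check_symmetric(M, "M")
  M <- (M + t(M)) / 2
  e <- eigen(M, symmetric = TRUE)
  if (min(e$values) >= floor) return(M)
  lam <- pmax(e$values, floor)
  M2 <- e$vectors %*% (lam * t(e$vectors))
  d_old <- diag(M)
  d_new <- diag(M2)
  bad <- d_new <= 0 & d_old != 0
  if (any(bad)) stop("cannot preserve diagonal")
  s <- ifelse(d_new > 0, sqrt(d_old / d_new), 0)
  out <- M2 * tcrossprod(s)
  out <- (out + t(out)) / 2
  diag(out) <- d_old
  dimnames(out) <- dimnames(M)
  out
}

#' Bivariate random-effects covariance from four correlations
#'
#' Builds the 4 x 4 random-effects covariance (intercept and slope for each
#' of two measures) used throughout the bivariate grid study. Diagonal
#' variances are fixed by the scenario: case A and B use
#' `diag = (1, 1, 1, 1)`; case C uses `diag = (1, 1, 1, 4)` so the second
#' measure's slope is markedly more heterogeneous. Within-measure
#' intercept-slope correlations are `rho_k1` and `rho_k2`; every one of the
#' four cross-measure entries shares the single between-measure correlation
#' `rho_b`. Because four free correlations can produce an indefinite matrix,
#' the raw construction is passed through [psd_repair()].
#'
#' @param case `"A"`, `"B"` or `"C"`.
#' @param rho_b cross-measure random-effect correlation, in \[-1, 1\].
#' @param rho_k1,rho_k2 within-measure intercept-slope correlations.
#' @return 4 x 4 symmetric PSD matrix.
#' @export
build_bivariate_D <- function(case = c("A", "B", "C"), rho_b, rho_k1, rho_k2) {
  case <- match.arg(case)
  stopifnot(abs(rho_b) <= 1, abs(rho_k1) <= 1, abs(rho_k2) <= 1)
  d <- if (case == "C") c(1, 1, 1, 4) else c(1, 1, 1, 1)
  C <- diag(4)
  C[1, 2] <- C[2, 1] <- rho_k1
  C[3, 4] <- C[4, 3] <- rho_k2
  C[1:2, 3:4] <- rho_b
  C[3:4, 1:2] <- rho_b
  s <- sqrt(d)
  psd_repair(C * tcrossprod(s))
}

#' Bivariate residual covariance from one correlation
#'
#' 2 x 2 per-observation residual covariance of the two measures. The first
#' measure always has unit error variance; case B uses `r22 = 4` (noisier
#' second measure), cases A and C use `r22 = 1`.
#'
#' @param case `"A"`, `"B"` or `"C"`.
#' @param rho_r residual cross-measure correlation, in \[-1, 1\].
#' @return 2 x 2 symmetric PSD matrix.
#' @export
build_bivariate_R <- function(case = c("A", "B", "C"), rho_r) {
  case <- match.arg(case)
  stopifnot(abs(rho_r) <= 1)
  r22 <- if (case == "B") 4 else 1
  matrix(c(1, rho_r * sqrt(r22), rho_r * sqrt(r22), r22), 2, 2)
}

#' Subject-level residual covariance
#'
#' Expands the K x K per-observation residual covariance R into the n_i x n_i
#' covariance of the stacked error vector. Within a measure, errors are
#' independent with variance `R[k, k]`. Across measures, two observations are
#' correlated (covariance `R[k, k']`) only when they were recorded at the
#' same time, up to a tie tolerance; errors of non-simultaneous observations
#' are independent.
#'
#' @param subject a `subject_design`.
#' @param R K x K symmetric PSD matrix.
#' @param tie_tol absolute time difference below which two observation times
#'   count as simultaneous.
#' @return n_i x n_i symmetric PSD matrix.
#' @export
build_residual_cov <- function(subject, R, tie_tol = 1e-9) {
  stopifnot(inherits(subject, "subject_design"))
  R <- as.matrix(R)
  K <- length(subject$markers)
  if (nrow(R) != K) stop("R dimension does not match the number of measures")
  n <- subject$n_i
  Sigma <- matrix(0, n, n)
  offs <- c(0L, cumsum(subject$n_ik))
  for (k in seq_len(K)) {
    rows_k <- offs[k] + seq_len(subject$n_ik[k])
    if (length(rows_k)) Sigma[rows_k, rows_k] <- R[k, k] * diag(length(rows_k))
    if (k == K) next
    tk <- subject$markers[[k]]$times
    for (l in (k + 1):K) {
      if (R[k, l] == 0) next
      tl <- subject$markers[[l]]$times
      rows_l <- offs[l] + seq_len(subject$n_ik[l])
      shared <- abs(outer(tk, tl, "-")) <= tie_tol
      if (any(shared)) {
        idx <- which(shared, arr.ind = TRUE)
        Sigma[cbind(rows_k[idx[, 1]], rows_l[idx[, 2]])] <- R[k, l]
        Sigma[cbind(rows_l[idx[, 2]], rows_k[idx[, 1]])] <- R[k, l]
      }
    }
  }
  Sigma
}

#' Marginal covariance of a subject's stacked observations
#'
#' Computes `V_i = Z_i D Z_i' + Sigma_i` and its inverse. Fails with an
#' informative error when V_i is numerically singular (e.g. a zero residual
#' variance combined with a degenerate D).
#'
#' @param subject a `subject_design`.
#' @param components a `covariance_components`.
#' @param Z optional pre-assembled Z_i (avoids re-assembly in hot loops).
#' @param Sigma optional pre-built residual covariance.
#' @return list with `V`, its inverse `W`, `Z` and `Sigma`.
#' @export
marginal_cov <- function(subject, components, Z = NULL, Sigma = NULL) {
  stopifnot(inherits(components, "covariance_components"))
  if (is.null(Z)) Z <- assemble_block_design(subject)$Z
  if (is.null(Sigma)) Sigma <- build_residual_cov(subject, components$R)
  V <- Z %*% components$D %*% t(Z) + Sigma
  V <- (V + t(V)) / 2
  ch <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(ch)) stop("degenerate marginal covariance")
  W <- chol2inv(ch)
  list(V = V, W = W, Z = Z, Sigma = Sigma)
}
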