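# evaluate code with a temporary RNG state, restoring the caller's stream
with_seed <- function(seed, code) {
  genv <- globalenv()
  old <- if (exists(".Random.seed", envir = genv, inherits = FALSE))
    get(".Random.seed", envir = genv) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  force(code)
}

# deterministic per-cell, per-draw seed below 2^31
derive_seed <- function(base_seed, cell_index, draw = 0L) {
  as.integer((as.double(base_seed) + 104729 * cell_index + draw) %% 2147483629)
}

#' Bivariate grid designs: equally spaced times and retained rows
#'
#' Measure 1 is observed at `n1` equally spaced times scaled to \[-1, 1\];
#' its random-effects design is `Z1 = [1, t]` (intercept and slope). Measure
#' 2 keeps `n2 = round((1 - pmiss) * n1)` of those rows: the first `n2`
#' under the drop-out pattern, or a uniformly drawn subset under the random
#' pattern. Times keep their full-grid values; the fixed-effects design
#' equals Z (beta is treated as known in the grid study).
#'
#' @param n1 number of observations of measure 1 (>= 2).
#' @param pmiss fraction of measure-2 rows missing.
#' @param pattern `"dropout"` or `"random"`.
#' @param seed integer seed for the random pattern.
#' @return list with `times`, `Z1`, `Z2`, and the retained row indices
#'   `keep2`.
#' @export
build_times_Z <- function(n1, pmiss = 0, pattern = c("dropout", "random"),
                          seed = 1L) {
  pattern <- match.arg(pattern)
  stopifnot(n1 >= 2, pmiss >= 0, pmiss < 1)
  n2 <- round((1 - pmiss) * n1)
  if (n2 < 1) stop("measure 2 fully missing")
  times <- seq(-1, 1, length.out = n1)
  Z1 <- cbind(intercept = 1, slope = times)
  keep2 <- if (pmiss == 0 || pattern == "dropout") seq_len(n2)
           else sort(with_seed(seed, sample.int(n1, n2)))
  list(times = times, Z1 = Z1, Z2 = Z1[keep2, , drop = FALSE], keep2 = keep2)
}

#' Grid cell of the bivariate efficiency study
#'
#' @param case `"A"`, `"B"` or `"C"`.
#' @param rho_b,rho_r,rho_k correlations (the common within-measure
#'   correlation `rho_k` is used for both measures).
#' @param n1 observations of measure 1.
#' @param pmiss missing fraction for measure 2 (0, 1/3 or 2/3 in the default
#'   grid).
#' @param pattern `"dropout"` or `"random"`.
#' @param pattern_seed base seed for random pattern draws.
#' @return object of class `grid_cell`.
#' @export
grid_cell <- function(case, rho_b, rho_r, rho_k, n1 = 6, pmiss = 0,
                      pattern = "random", pattern_seed = 1L) {
  structure(list(case = case, rho_b = rho_b, rho_r = rho_r, rho_k = rho_k,
                 n1 = n1, pmiss = pmiss, pattern = pattern,
                 pattern_seed = as.integer(pattern_seed)),
            class = "grid_cell")
}

#' Plausibility mask for correlation pairs
#'
#' Large cross-measure random-effect and residual correlations of opposite
#' sign are biologically implausible for markers tracking one disease
#' process; such cells are excluded from grid summaries. The default rule
#' flags `(rho_b, rho_r)` as unlikely when the signs differ and both
#' magnitudes are at least `min_abs`.
#'
#' @param rho_b,rho_r numeric vectors (recycled).
#' @param min_abs magnitude threshold of the rule.
#' @return logical vector: `TRUE` for likely (kept) combinations.
#' @export
likely_mask <- function(rho_b, rho_r, min_abs = 0.5) {
  !(sign(rho_b) * sign(rho_r) < 0 & pmin(abs(rho_b), abs(rho_r)) >= min_abs)
}

# Measure-2 random-effects bias^2/variance (coords 3:4) for both working
# models, beta known. Lean path used by the grid; the generic module
# reproduces it exactly (tested).
bivar_cell_mse <- function(Z1, keep2, D, R) {
  n1 <- nrow(Z1); n2 <- length(keep2)
  Z2 <- Z1[keep2, , drop = FALSE]
  n <- n1 + n2
  Z <- matrix(0, n, 4)
  Z[seq_len(n1), 1:2] <- Z1
  Z[n1 + seq_len(n2), 3:4] <- Z2
  Sig <- function(r12, r22) {
    S <- diag(c(rep(R[1, 1], n1), rep(r22, n2)))
    if (r12 != 0) {
      S[cbind(keep2, n1 + seq_len(n2))] <- r12
      S[cbind(n1 + seq_len(n2), keep2)] <- r12
    }
    S
  }
  Sigma_t <- Sig(R[1, 2], R[2, 2])
  D_sep <- D; D_sep[1:2, 3:4] <- 0; D_sep[3:4, 1:2] <- 0
  one <- function(D_w, Sigma_w) {
    V <- Z %*% D_w %*% t(Z) + Sigma_w
    L <- D_w %*% crossprod(Z, chol2inv(chol((V + t(V)) / 2)))
    Cb <- L %*% Z; diag(Cb) <- diag(Cb) - 1
    b2 <- rowSums((Cb %*% D) * Cb)[3:4]
    v <- rowSums((L %*% Sigma_t) * L)[3:4]
    c(bias2 = sum(b2), var = sum(v))
  }
  list(C = one(D, Sigma_t), S = one(D_sep, Sig(0, R[2, 2])))
}

#' Evaluate one grid cell
#'
#' Builds the scenario's covariance components and designs, computes the
#' exact random-effects MSE decomposition of the measure-2 block (intercept
#' and slope of the sparser measure) under both working models with beta
#' known, and returns their ratio. For the random pattern with `pmiss > 0`
#' the MSEs are averaged over `n_pattern_draws` seeded pattern draws before
#' the ratio is formed; drop-out and complete-data cells are deterministic.
#'
#' @param cell a `grid_cell`.
#' @param n_pattern_draws number of seeded random-pattern draws.
#' @return object of class `grid_result`: the cell plus `ratio_b2`, the
#'   (averaged) decompositions of both models and the `likely` flag.
#' @export
evaluate_cell <- function(cell, n_pattern_draws = 20) {
  stopifnot(inherits(cell, "grid_cell"))
  D <- build_bivariate_D(cell$case, cell$rho_b, cell$rho_k, cell$rho_k)
  R <- build_bivariate_R(cell$case, cell$rho_r)
  stochastic <- cell$pattern == "random" && cell$pmiss > 0
  draws <- if (stochastic) seq_len(n_pattern_draws) else 1L
  acc <- list(C = c(bias2 = 0, var = 0), S = c(bias2 = 0, var = 0))
  for (d in draws) {
    bt <- build_times_Z(cell$n1, cell$pmiss, cell$pattern,
                        seed = derive_seed(cell$pattern_seed, 0L, d))
    m <- bivar_cell_mse(bt$Z1, bt$keep2, D, R)
    acc$C <- acc$C + m$C / length(draws)
    acc$S <- acc$S + m$S / length(draws)
  }
  structure(list(cell = cell,
                 ratio_b2 = sum(acc$C) / sum(acc$S),
                 decomposition_C = acc$C, decomposition_S = acc$S,
                 likely = likely_mask(cell$rho_b, cell$rho_r)),
            class = "grid_result")
}

#' Default correlation grid of the bivariate study
#'
#' @return data.frame enumerating the full factorial default grid.
#' @export
default_grid_spec <- function(cases = c("A", "B", "C"),
                              pmiss = c(0, 1/3, 2/3),
                              n1 = c(6, 9, 15),
                              rho_k = c(-0.5, 0, 0.5),
                              rho_b = seq(-0.9, 0.9, by = 0.2),
                              rho_r = seq(-0.9, 0.9, by = 0.2),
                              pattern = "random") {
  expand.grid(case = cases, pattern = pattern, pmiss = pmiss, n1 = n1,
              rho_k = rho_k, rho_b = rho_b, rho_r = rho_r,
              KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
}

#' Run the bivariate grid study
#'
#' Evaluates every cell of a grid specification and returns one row per cell
#' with the MSE ratio of the measure-2 random effects, its bias/variance
#' decomposition under both working models, and the plausibility flag.
#'
#' @param spec data.frame as produced by [default_grid_spec()].
#' @param n_pattern_draws seeded random-pattern draws per stochastic cell.
#' @param base_seed integer; all pattern seeds derive deterministically from
#'   it and the cell index.
#' @return data.frame of grid results.
#' @export
run_grid <- function(spec = default_grid_spec(), n_pattern_draws = 20,
                     base_seed = 1L) {
  res <- vector("list", nrow(spec))
  for (i in seq_len(nrow(spec))) {
    cl <- grid_cell(spec$case[i], spec$rho_b[i], spec$rho_r[i], spec$rho_k[i],
                    n1 = spec$n1[i], pmiss = spec$pmiss[i],
                    pattern = spec$pattern[i],
                    pattern_seed = derive_seed(base_seed, i))
    r <- evaluate_cell(cl, n_pattern_draws)
    res[[i]] <- data.frame(
      spec[i, , drop = FALSE],
      ratio_b2 = r$ratio_b2,
      bias2_C = r$decomposition_C[["bias2"]], var_C = r$decomposition_C[["var"]],
      bias2_S = r$decomposition_S[["bias2"]], var_S = r$decomposition_S[["var"]],
      likely = r$likely, row.names = NULL)
  }
  do.call(rbind, res)
}

#' Summarize grid results over likely cells
#'
#' Five-number summaries of the measure-2 MSE ratio grouped by scenario,
#' missingness and sample size, restricted to the likely correlation
#' combinations (the boxplot-style aggregation of the grid study).
#'
#' @param results data.frame from [run_grid()].
#' @param groupby grouping columns.
#' @param likely_only drop implausible cells first (default `TRUE`).
#' @return data.frame with min/q25/median/q75/max and cell counts.
#' @export
summarize_grid <- function(results, groupby = c("case", "pmiss", "n1"),
                           likely_only = TRUE) {
  if (likely_only) results <- results[results$likely, , drop = FALSE]
  if (nrow(results) == 0) stop("empty selection")
  key <- interaction(results[groupby], drop = TRUE, lex.order = TRUE)
  out <- do.call(rbind, lapply(split(results, key), function(g) {
    qs <- stats::quantile(g$ratio_b2, c(0, .25, .5, .75, 1), names = FALSE)
    cbind(g[1, groupby, drop = FALSE],
          data.frame(min = qs[1], q25 = qs[2], median = qs[3], q75 = qs[4],
                     max = qs[5], n_cells = nrow(g)))
  }))
  rownames(out) <- NULL
  out
}

#' Long-format heatmap table of the ratio over the correlation plane
#'
#' One row per (rho_b, rho_r) cell for each (case, pmiss) panel at fixed
#' `n1` and `rho_k`, mirroring the grid study's heatmap figures.
#'
#' @param results data.frame from [run_grid()].
#' @param n1,rho_k panel values to extract.
#' @return data.frame with columns case, pmiss, rho_b, rho_r, ratio_b2,
#'   likely.
#' @export
heatmap_long <- function(results, n1 = 6, rho_k = 0) {
  sel <- results$n1 == n1 & abs(results$rho_k - rho_k) < 1e-12
  if (!any(sel)) stop("empty selection")
  out <- results[sel, c("case", "pmiss", "rho_b", "rho_r", "ratio_b2", "likely")]
  out[order(out$case, out$pmiss, out$rho_b, out$rho_r), ]
}
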