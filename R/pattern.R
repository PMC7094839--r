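#' Residualize data on confounders via orthogonal projection
#'
#' Applies the projection complement `I - C (C'C)^-1 C'` along the subject
#' dimension, with an intercept column appended to `C` so that means are
#' removed along with the confounder directions (Z-scored confounders are
#' mean-zero, but the data are not). Accepts a subjects-length vector or a
#' regions x subjects matrix (each row residualized across subjects).
#'
#' @param x numeric vector (length n) or matrix (regions x n).
#' @param confounders subjects x q matrix ([standardize_covariates()]).
#' @param intercept append an intercept column to the confounder block.
#' @return Same shape as `x`, orthogonal to every confounder column.
#' @export
residualize <- function(x, confounders, intercept = TRUE) {
  C <- as.matrix(unclass(confounders))
  if (intercept) C <- cbind(1, C)
  qx <- qr(C)
  if (qx$rank < ncol(C))
    stop("rank-deficient confounder matrix", call. = FALSE)
  if (is.matrix(x)) {
    if (ncol(x) != nrow(C)) stop("subject dimension mismatch")
    out <- t(qr.resid(qx, t(x)))
    dimnames(out) <- dimnames(x)
    out
  } else {
    if (length(x) != nrow(C)) stop("subject dimension mismatch")
    as.vector(qr.resid(qx, x))
  }
}

#' Remove the grand-mean thickness pattern
#'
#' Subtracts each subject's across-region mean (every subject profile then
#' sums to zero) and afterwards the group-mean residual image. The result
#' has rank at most 67 = 68 - 1: the all-ones direction in region space is
#' annihilated, so one principal component is lost.
#'
#' @param thx regions x subjects matrix (a `thickness_matrix` or plain).
#' @return Centered regions x subjects matrix (plain).
#' @export
remove_grand_mean_pattern <- function(thx) {
  x <- as.matrix(unclass(thx))
  x <- sweep(x, 2, colMeans(x))   # per-subject mean profile out
  x - rowMeans(x)                 # group-mean residual image out
}

#' Principal components of a residualized thickness array
#'
#' SVD-based PCA in region space: `x = components %*% t(scores)` with
#' orthonormal `components` (regions x K) and `scores` (subjects x K),
#' ordered by descending singular value. Components with singular value
#' below `tol` times the largest are dropped. The sign of each component is
#' fixed by making its largest-magnitude loading positive.
#'
#' @param x regions x subjects matrix, centered and residualized.
#' @param tol relative singular-value tolerance for the numerical rank.
#' @return List (`pca_basis`): `components`, `scores`, `singular_values`.
#' @export
thickness_pca <- function(x, tol = 1e-8) {
  x <- as.matrix(unclass(x))
  sv <- svd(x)
  keep <- sv$d > tol * sv$d[1]
  kmax <- min(sum(keep), nrow(x) - 1, ncol(x) - 1)
  keep <- seq_len(kmax)
  comp <- sv$u[, keep, drop = FALSE]
  scores <- sv$v[, keep, drop = FALSE] %*% diag(sv$d[keep], kmax)
  flip <- vapply(seq_len(kmax),
                 function(k) comp[which.max(abs(comp[, k])), k] < 0,
                 logical(1))
  comp[, flip] <- -comp[, flip]
  scores[, flip] <- -scores[, flip]
  rownames(comp) <- rownames(x)
  structure(list(components = comp, scores = scores,
                 singular_values = sv$d[keep]),
            class = "pca_basis")
}

#' Select the number of components by leave-one-out PRESS
#'
#' For each candidate k, regresses the residualized dependent variable on
#' the leading k principal-component scores (plus intercept) and computes
#' the mean squared leave-one-out prediction error via the hat-matrix
#' identity `e_loo = e / (1 - h)`. Only the leading sets PC1..PCk are
#' candidates. K is the PRESS minimizer; ties go to the smaller k.
#'
#' @param basis a `pca_basis`.
#' @param r_dv residualized dependent variable (subjects vector).
#' @param k_max largest candidate k.
#' @return List: `K` (selected), `press` (mean PRESS per candidate k).
#' @export
select_k_press <- function(basis, r_dv, k_max = 15) {
  W <- basis$scores
  n <- nrow(W)
  k_max <- min(k_max, ncol(W))
  if (k_max >= n - 2) stop("k_max must be below n - 2")
  press <- vapply(seq_len(k_max), function(k) {
    Z <- cbind(1, W[, seq_len(k), drop = FALSE])
    qz <- qr(Z)
    e <- qr.resid(qz, r_dv)
    Qz <- qr.Q(qz)
    h <- rowSums(Qz^2)
    mean((e / (1 - h))^2)
  }, numeric(1))
  # smallest k on numerical ties (e.g. noiseless fits where PRESS ~ 0),
  # judged on the scale of the dependent variable
  tol <- 1e-10 * mean(r_dv^2)
  K <- which(press <= min(press) + tol)[1]
  list(K = K, press = press)
}

#' Derive the covariate-adjusted thickness pattern
#'
#' Regresses the residualized dependent variable on the leading K component
#' scores (plus intercept), maps the regression weights back to region
#' space (`v = V[, 1:K] beta`), normalizes the loading vector to unit L2
#' norm, and computes subject scores as the projection of the residualized
#' data onto the pattern. The fit is summarized by the Pearson correlation
#' between subject scores and the dependent variable with a parametric
#' two-sided p at n - 2 df.
#'
#' @param basis a `pca_basis` of the residualized thickness.
#' @param r_dv residualized dependent variable.
#' @param K number of leading components (e.g. from [select_k_press()]).
#' @param press_curve optional PRESS curve to carry along.
#' @return List (`pattern_result`): `loadings` (unit L2 norm),
#'   `subject_scores`, `K`, `regression_weights`, `fit_R`, `fit_p`,
#'   `press_curve`.
#' @export
derive_pattern <- function(basis, r_dv, K, press_curve = NULL) {
  stopifnot(K >= 1, K <= ncol(basis$scores))
  W <- basis$scores[, seq_len(K), drop = FALSE]
  Z <- cbind(1, W)
  beta <- qr.coef(qr(Z), r_dv)
  v <- basis$components[, seq_len(K), drop = FALSE] %*% beta[-1]
  nv <- sqrt(sum(v^2))
  if (nv == 0) stop("degenerate pattern: zero regression weights")
  v <- v / nv
  # w = rTHX' v expressed through the basis (exact: rTHX = U diag(d) V')
  w <- basis$scores %*% crossprod(basis$components, v)
  r <- stats::cor(w, r_dv)[1, 1]
  n <- length(r_dv)
  tstat <- r * sqrt((n - 2) / max(1 - r^2, .Machine$double.eps))
  structure(list(loadings = stats::setNames(as.vector(v), rownames(basis$components)),
                 subject_scores = as.vector(w), K = K,
                 regression_weights = beta[-1],
                 fit_R = r, fit_p = 2 * stats::pt(-abs(tstat), n - 2),
                 press_curve = press_curve),
            class = "pattern_result")
}

#' Project a pattern onto (new) residualized thickness data
#'
#' @param pattern a `pattern_result`.
#' @param r_thx regions x subjects residualized thickness matrix.
#' @return Numeric vector of subject scores.
#' @export
score_subjects <- function(pattern, r_thx) {
  as.vector(crossprod(as.matrix(unclass(r_thx)), pattern$loadings))
}

# Fast PCA for bootstrap resamples: eigen of the region-space covariance.
# Returns leading-K orthonormal components and subject scores.
pca_fit_k <- function(x, K) {
  s <- tcrossprod(x)
  e <- eigen(s, symmetric = TRUE)
  if (e$values[K] <= 1e-12 * e$values[1]) return(NULL)  # rank collapse
  comp <- e$vectors[, seq_len(K), drop = FALSE]
  list(components = comp, scores = crossprod(x, comp))
}

#' Bootstrap percentile intervals for pattern loadings
#'
#' Resamples subjects with replacement (pairing the residualized dependent
#' variable with the residualized thickness profiles), reruns PCA and the
#' pattern regression with K fixed at the point estimate's selection,
#' sign-aligns each bootstrap pattern to the point estimate (flips when the
#' inner product is negative), and reports per-region [2.5%, 97.5%]
#' percentile intervals. A region is flagged robust when its interval
#' excludes zero. Degenerate resamples (rank collapse or constant dependent
#' variable) are redrawn and counted.
#'
#' @param r_thx regions x subjects residualized thickness.
#' @param r_dv residualized dependent variable.
#' @param K component count, fixed across iterations (use
#'   `reselect_k = TRUE` for per-iteration PRESS re-selection).
#' @param n_boot number of bootstrap iterations (>= 100).
#' @param seed RNG seed.
#' @param point loadings to sign-align against (defaults to the pattern
#'   derived from the full sample).
#' @param reselect_k re-run PRESS selection within each resample.
#' @param k_max candidate limit when `reselect_k` is used.
#' @return data.frame per region: `region`, `loading` (point estimate),
#'   `lower`, `upper`, `robust`. Attributes: `n_boot`, `seed`,
#'   `n_redrawn`, `boot_K` (per-iteration K).
#' @export
bootstrap_loadings <- function(r_thx, r_dv, K, n_boot = 10000, seed = 1L,
                               point = NULL, reselect_k = FALSE,
                               k_max = 15) {
  x <- as.matrix(unclass(r_thx))
  n <- ncol(x)
  if (n_boot < 100) stop("n_boot must be >= 100")
  if (is.null(point)) {
    basis <- thickness_pca(x)
    point <- derive_pattern(basis, r_dv, K)$loadings
  }
  redrawn <- 0L
  boot_k <- integer(n_boot)
  loads <- with_seed(seed, {
    out <- matrix(NA_real_, nrow(x), n_boot)
    b <- 1L
    while (b <= n_boot) {
      idx <- sample.int(n, n, replace = TRUE)
      xb <- x[, idx, drop = FALSE]
      xb <- xb - rowMeans(xb)           # re-center the resampled group mean
      dvb <- r_dv[idx]
      kb <- K
      fit <- pca_fit_k(xb, max(kb, if (reselect_k) k_max else kb))
      ok <- !is.null(fit) && stats::sd(dvb) > 0
      if (ok && reselect_k) {
        bb <- structure(list(components = fit$components,
                             scores = fit$scores), class = "pca_basis")
        kb <- select_k_press(bb, dvb, min(k_max, ncol(fit$scores)))$K
      }
      if (ok) {
        W <- fit$scores[, seq_len(kb), drop = FALSE]
        beta <- qr.coef(qr(cbind(1, W)), dvb)
        v <- fit$components[, seq_len(kb), drop = FALSE] %*% beta[-1]
        nv <- sqrt(sum(v^2))
        ok <- is.finite(nv) && nv > 0
        if (ok) {
          v <- v / nv
          if (sum(v * point) < 0) v <- -v
          out[, b] <- v
          boot_k[b] <- kb
          b <- b + 1L
        }
      }
      if (!ok) redrawn <- redrawn + 1L
    }
    out
  })
  qs <- apply(loads, 1, stats::quantile, probs = c(0.025, 0.975),
              names = FALSE)
  nm <- names(point)
  if (is.null(nm)) nm <- rownames(x)
  if (is.null(nm)) nm <- sprintf("region%02d", seq_len(nrow(x)))
  res <- data.frame(region = nm, loading = as.vector(point),
                    lower = qs[1, ], upper = qs[2, ],
                    stringsAsFactors = FALSE)
  res$robust <- res$lower > 0 | res$upper < 0
  attr(res, "n_boot") <- n_boot
  attr(res, "seed") <- seed
  attr(res, "n_redrawn") <- redrawn
  attr(res, "boot_K") <- boot_k
  res
}

#' Subject-wise residual signal orthogonal to a pattern
#'
#' Decomposes the residualized thickness as `r_thx = v w' + E` and returns
#' the per-subject mean of squared residuals over the 68 regions.
#'
#' @param r_thx regions x subjects residualized thickness.
#' @param pattern a `pattern_result` derived from the same data.
#' @return Numeric vector (subjects), the residual sum-of-squares profile.
#' @export
residual_signal <- function(r_thx, pattern) {
  x <- as.matrix(unclass(r_thx))
  E <- x - pattern$loadings %*% t(pattern$subject_scores)
  colMeans(E^2)
}

#' Regress residual signal on the covariates
#'
#' OLS of the per-subject residual sum of squares on an intercept plus the
#' Z-scored covariates, with two-sided t-tests — positive age or motion
#' coefficients indicate that the derived pattern explains less of the
#' thickness variation in older or higher-motion subjects.
#'
#' @param ress vector from [residual_signal()].
#' @param cov subjects x p covariate matrix ([standardize_covariates()]).
#' @return data.frame per covariate: `covariate`, `beta`, `t`, `p`.
#' @export
ress_regression <- function(ress, cov) {
  fit <- ols_multi(matrix(ress, ncol = 1, dimnames = list(NULL, "ress")), cov)
  covariates <- colnames(cov)
  out <- data.frame(covariate = covariates,
                    beta = fit$beta[covariates, 1],
                    t = fit$t[covariates, 1],
                    p = fit$p[covariates, 1],
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "df") <- fit$df
  out
}

#' Covariate-adjusted PCA-regression of thickness on a dependent variable
#'
#' The full Scaled-Subprofile-Model-style chain: grand-mean-pattern
#' removal, residualization of thickness and dependent variable on the
#' confounders, PCA, PRESS-based selection of the number of leading
#' components, pattern derivation with unit-norm loadings and subject
#' scores, optional bootstrap percentile intervals, and the regression of
#' pattern-orthogonal residual signal on all covariates. Swapping the roles
#' of the dependent variable and a confounder (education vs. cognition)
#' runs the identical code path.
#'
#' The subject scores are orthogonal to every confounder by construction;
#' this is asserted (|r| < 1e-8) on every run.
#'
#' @param thx a `thickness_matrix`.
#' @param cov subjects x 5 covariate matrix containing `dv` and the
#'   confounders.
#' @param dv dependent-variable column name (default `"education"`).
#' @param k_max largest candidate component count for PRESS.
#' @param n_boot bootstrap iterations (0 skips the bootstrap).
#' @param seed RNG seed for the bootstrap.
#' @param reselect_k re-select K within each bootstrap resample.
#' @return List (`ssm_result`): `pattern` (a `pattern_result`), `K`,
#'   `press`, `bootstrap` (or NULL), `ress`, `ress_stats`, `r_thx`, `r_dv`,
#'   `confounders` (names), `dv`.
#' @export
ssm_pattern <- function(thx, cov, dv = "education", k_max = 15,
                        n_boot = 0, seed = 1L, reselect_k = FALSE) {
  cov_m <- as.matrix(unclass(cov))
  if (!dv %in% colnames(cov_m)) stop("dv '", dv, "' not in covariates")
  conf <- cov_m[, setdiff(colnames(cov_m), dv), drop = FALSE]
  x <- remove_grand_mean_pattern(thx)
  r_thx <- residualize(x, conf)
  r_dv <- residualize(cov_m[, dv], conf)
  basis <- thickness_pca(r_thx)
  sel <- select_k_press(basis, r_dv, min(k_max, ncol(basis$scores)))
  pattern <- derive_pattern(basis, r_dv, sel$K, press_curve = sel$press)
  adj <- abs(stats::cor(pattern$subject_scores, conf))
  if (any(adj > 1e-8))
    stop("adjustment guarantee violated: subject scores correlate with a ",
         "confounder (max |r| = ", format(max(adj)), ")")
  boot <- NULL
  if (n_boot > 0) {
    boot <- bootstrap_loadings(r_thx, r_dv, K = sel$K, n_boot = n_boot,
                               seed = seed, point = pattern$loadings,
                               reselect_k = reselect_k, k_max = k_max)
  }
  ress <- residual_signal(r_thx, pattern)
  structure(list(pattern = pattern, K = sel$K, press = sel$press,
                 bootstrap = boot, ress = ress,
                 ress_stats = ress_regression(ress, cov_m),
                 r_thx = r_thx, r_dv = r_dv,
                 confounders = colnames(conf), dv = dv),
            class = "ssm_result")
}
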