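#' Region-wise multiple regression of thickness on covariates
#'
#' Fits, for each of the 68 regions independently, the model
#' `thickness ~ 1 + education + gender + cognition + rFD + age` with
#' Z-standardized covariates (the intercept is added internally; with p
#' covariates the residual df is n - p - 1). Coefficients are in mm per SD
#' of the covariate; p-values are two-sided t-tests.
#'
#' @param thx a `thickness_matrix` (regions x subjects).
#' @param cov subjects x p covariate matrix from
#'   [standardize_covariates()].
#' @param fdr_q FDR level for the Benjamini-Hochberg flag.
#' @param fdr_scope `"per_covariate"` (step-up across the 68 regions within
#'   each covariate, matching per-covariate region counts) or `"pooled"`
#'   (one correction across all region x covariate tests).
#' @return data.frame with one row per (region, covariate): `region`,
#'   `covariate`, `beta`, `t`, `p`, `fdr_significant`. Attribute `df`
#'   carries the residual degrees of freedom.
#' @export
fit_regionwise <- function(thx, cov, fdr_q = 0.05,
                           fdr_scope = c("per_covariate", "pooled")) {
  fdr_scope <- match.arg(fdr_scope)
  y <- t(unclass(thx))                    # subjects x regions
  fit <- ols_multi(y, cov)
  covariates <- colnames(cov)
  out <- data.frame(
    region = rep(rownames(thx), each = length(covariates)),
    covariate = rep(covariates, times = nrow(thx)),
    beta = as.vector(fit$beta[covariates, ]),
    t = as.vector(fit$t[covariates, ]),
    p = as.vector(fit$p[covariates, ]),
    stringsAsFactors = FALSE)
  out$fdr_significant <- FALSE
  if (fdr_scope == "per_covariate") {
    for (cv in covariates) {
      i <- out$covariate == cv
      out$fdr_significant[i] <- fdr_bh(out$p[i], fdr_q)$significant
    }
  } else {
    out$fdr_significant <- fdr_bh(out$p, fdr_q)$significant
  }
  attr(out, "df") <- fit$df
  attr(out, "fdr_q") <- fdr_q
  out
}

#' Mean-thickness regression
#'
#' The same model as [fit_regionwise()], with the per-subject mean over the
#' 68 regions as the single dependent variable.
#'
#' @inheritParams fit_regionwise
#' @return data.frame with one row per covariate: `covariate`, `beta`, `t`,
#'   `p`.
#' @export
fit_mean_thickness <- function(thx, cov) {
  y <- matrix(colMeans(unclass(thx)), ncol = 1,
              dimnames = list(NULL, "mean_thickness"))
  fit <- ols_multi(y, cov)
  covariates <- colnames(cov)
  out <- data.frame(covariate = covariates,
                    beta = fit$beta[covariates, 1],
                    t = fit$t[covariates, 1],
                    p = fit$p[covariates, 1],
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "df") <- fit$df
  out
}

# Shared OLS core: y (n x m responses) on intercept + cov, with per-response
# t statistics. Errors on rank deficiency, naming the collinear columns.
ols_multi <- function(y, cov) {
  cov <- as.matrix(unclass(cov))
  n <- nrow(cov)
  if (nrow(y) != n) stop("response/covariate row mismatch")
  X <- cbind("(intercept)" = 1, cov)
  p <- ncol(X)
  if (n <= p) stop("need n > p + 1 subjects for the fit")
  qx <- qr(X)
  if (qx$rank < p) {
    bad <- colnames(X)[qx$pivot[(qx$rank + 1):p]]
    stop("rank-deficient design; collinear columns: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  beta <- qr.coef(qx, y)                  # p x m
  res <- y - X %*% beta
  df <- n - p
  sigma2 <- colSums(res^2) / df
  xtx_inv <- solve(crossprod(X))
  se <- sqrt(outer(diag(xtx_inv), sigma2))
  tval <- beta / se
  pval <- 2 * stats::pt(-abs(tval), df)
  dimnames(beta) <- dimnames(tval) <- dimnames(pval) <-
    list(colnames(X), colnames(y))
  list(beta = beta, t = tval, p = pval, df = df, residuals = res)
}

#' Benjamini-Hochberg step-up FDR control
#'
#' Sorts the p-values ascending, finds the largest rank k with
#' `p_(k) <= k q / m`, and rejects all hypotheses of rank <= k.
#'
#' @param pvals vector of p-values in \[0, 1\].
#' @param q target false discovery rate.
#' @return List with `significant` (logical mask in input order) and
#'   `threshold` (the largest rejected p-value, `NA` if none).
#' @export
fdr_bh <- function(pvals, q = 0.05) {
  if (!length(pvals)) return(list(significant = logical(0), threshold = NA_real_))
  if (anyNA(pvals) || any(pvals < 0 | pvals > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  sig <- stats::p.adjust(pvals, method = "BH") <= q
  list(significant = sig,
       threshold = if (any(sig)) max(pvals[sig]) else NA_real_)
}
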