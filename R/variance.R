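#' Median split of a covariate
#'
#' HIGH = strictly above the sample median; values tied with the median go
#' to LOW (a deterministic, stable convention). Errors if either group has
#' fewer than 2 members, since a group variance is then undefined.
#'
#' @param values numeric covariate vector (>= 4 subjects).
#' @return Factor with levels `LOW`, `HIGH`, one per subject.
#' @export
median_split <- function(values) {
  if (length(values) < 4) stop("need at least 4 subjects for a median split")
  g <- factor(ifelse(values > stats::median(values), "HIGH", "LOW"),
              levels = c("LOW", "HIGH"))
  if (any(table(g) < 2))
    stop("median split leaves a group with fewer than 2 subjects ",
         "(variance undefined)", call. = FALSE)
  g
}

#' Region-wise log variance-ratio statistic
#'
#' For each region, the natural log of the ratio of inter-subject sample
#' variances (n - 1 denominator) of residual thickness between the HIGH and
#' LOW groups: `log(var_HIGH / var_LOW)`.
#'
#' @param residual_thx regions x subjects matrix of residualized thickness.
#' @param groups factor from [median_split()], aligned with subjects.
#' @return Numeric vector, one log-F per region.
#' @export
logf_statistic <- function(residual_thx, groups) {
  residual_thx <- as.matrix(residual_thx)
  groups <- factor(groups, levels = c("LOW", "HIGH"))
  if (ncol(residual_thx) != length(groups))
    stop("groups length must match subjects")
  if (any(table(groups) < 2)) stop("both groups need >= 2 subjects")
  v <- function(idx) {
    x <- residual_thx[, idx, drop = FALSE]
    rowSums((x - rowMeans(x))^2) / (sum(idx) - 1)
  }
  vlow <- v(groups == "LOW")
  if (any(vlow == 0)) stop("zero residual variance in the LOW group")
  log(v(groups == "HIGH") / vlow)
}

#' Permutation test for covariate-related thickness-variance differences
#'
#' Residualizes thickness on all covariates except the covariate of
#' interest (plus an intercept), median-splits subjects on the covariate of
#' interest, and computes the region-wise log variance ratio
#' (HIGH over LOW). The null distribution is built by randomly permuting
#' the assignment between the thickness array and the whole covariate table
#' and redoing residualization and statistic each iteration, which
#' preserves the covariate intercorrelations under the null. Two-tailed
#' p-values use the add-one rule `p = (1 + #{|stat_perm| >= |stat_obs|}) /
#' (n_perm + 1)`; the alternative tail rule doubles the smaller empirical
#' tail.
#'
#' @param thx a `thickness_matrix`.
#' @param cov subjects x p covariate matrix ([standardize_covariates()]).
#' @param interest name of the covariate defining the split.
#' @param n_perm number of permutations (>= 100).
#' @param seed RNG seed for the permutations.
#' @param tail `"absolute"` (|log-F| comparison) or `"double"` (doubled
#'   empirical tail).
#' @param fdr_q level for the Benjamini-Hochberg flag across regions.
#' @return data.frame per region: `region`, `log_f`, `p_perm`, `p_param`
#'   (two-sided parametric F-test, diagnostic only), `fdr_significant`.
#'   Attributes: `n_low`, `n_high`, `n_perm`, `seed`, `interest`.
#' @export
variance_permutation_test <- function(thx, cov, interest,
                                      n_perm = 10000, seed = 1L,
                                      tail = c("absolute", "double"),
                                      fdr_q = 0.05) {
  tail <- match.arg(tail)
  cov <- as.matrix(unclass(cov))
  if (!interest %in% colnames(cov))
    stop("covariate of interest '", interest, "' not in the covariate matrix")
  if (n_perm < 100) stop("n_perm must be >= 100")
  n <- ncol(thx)
  if (nrow(cov) != n) stop("covariate/subject mismatch")
  nuis <- cov[, setdiff(colnames(cov), interest), drop = FALSE]
  groups <- median_split(cov[, interest])
  X <- t(unclass(thx))                    # subjects x regions
  # thin Q of [1 | nuisance]; residualization is X - Q (Q'X)
  qx <- qr(cbind(1, nuis))
  if (qx$rank < ncol(nuis) + 1) stop("rank-deficient nuisance design")
  Q <- qr.Q(qx)
  resid_rows <- function(Xs) Xs - Q %*% crossprod(Q, Xs)
  obs <- logf_statistic(t(resid_rows(X)), groups)
  ilow <- which(groups == "LOW"); ihigh <- which(groups == "HIGH")
  stat_of <- function(R) {
    gv <- function(idx) {
      xs <- R[idx, , drop = FALSE]
      colSums(xs^2) / (length(idx) - 1) -
        colSums(xs)^2 / (length(idx) * (length(idx) - 1))
    }
    log(gv(ihigh) / gv(ilow))
  }
  perm_stats <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      stat_of(resid_rows(X[sample.int(n), , drop = FALSE]))
    }, numeric(nrow(thx)))
  })
  if (is.null(dim(perm_stats)))
    perm_stats <- matrix(perm_stats, nrow = nrow(thx))
  if (tail == "absolute") {
    exceed <- rowSums(abs(perm_stats) >= abs(obs))
    p <- (1 + exceed) / (n_perm + 1)
  } else {
    hi <- rowSums(perm_stats >= obs)
    lo <- rowSums(perm_stats <= obs)
    p <- pmin(1, 2 * (1 + pmin(hi, lo)) / (n_perm + 1))
  }
  n1 <- length(ihigh); n2 <- length(ilow)
  p_param <- 2 * pmin(stats::pf(exp(obs), n1 - 1, n2 - 1),
                      1 - stats::pf(exp(obs), n1 - 1, n2 - 1))
  out <- data.frame(region = rownames(thx), log_f = obs, p_perm = p,
                    p_param = p_param,
                    fdr_significant = fdr_bh(p, fdr_q)$significant,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "n_low") <- n2
  attr(out, "n_high") <- n1
  attr(out, "n_perm") <- n_perm
  attr(out, "seed") <- seed
  attr(out, "interest") <- interest
  out
}
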