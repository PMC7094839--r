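test_that("residualization equals per-column OLS residuals and is a projector", {
  corthick:::with_seed(1, {
    for (i in 1:20) {
      n <- sample(20:60, 1)
      C <- matrix(rnorm(n * 4), n, 4)
      X <- matrix(rnorm(12 * n), 12, n)
      R <- residualize(X, C)
      for (r in sample(12, 3)) {
        oracle <- residuals(lm(X[r, ] ~ C))
        expect_lt(max(abs(R[r, ] - oracle)), 1e-10)
      }
      # idempotence and annihilation
      expect_lt(max(abs(residualize(R, C) - R)), 1e-12)
      inC <- as.vector(C %*% c(1, -1, 2, 0.5)) + 3
      expect_lt(max(abs(residualize(inC, C))), 1e-10)
      # output orthogonal to every confounder column and to the intercept
      expect_lt(max(abs(R %*% cbind(1, C))), 1e-8)
    }
  })
  expect_error(residualize(matrix(1, 3, 10),
                           cbind(1:10, 2 * (1:10))), "rank-deficient")
})

test_that("grand-mean-pattern removal centers profiles and drops one rank", {
  corthick:::with_seed(2, {
    x <- matrix(rnorm(68 * 100, 2.5, 0.3), 68, 100)
    cx <- remove_grand_mean_pattern(x)
    expect_lt(max(abs(colSums(cx))), 1e-10)
    d <- svd(cx)$d
    expect_equal(sum(d > 1e-8 * d[1]), 67)   # exactly 68 - 1 components
    # constant-per-subject input is annihilated
    const <- matrix(rep(runif(100, 2, 3), each = 68), 68)
    expect_lt(max(abs(remove_grand_mean_pattern(const))), 1e-12)
  })
})

test_that("PCA reconstructs the data and matches the covariance eigenbasis", {
  x <- corthick:::with_seed(3, {
    remove_grand_mean_pattern(matrix(rnorm(68 * 40, 2.5, 0.2), 68, 40))
  })
  b <- thickness_pca(x)
  expect_lt(max(abs(crossprod(b$components) - diag(ncol(b$components)))),
            1e-10)
  expect_lt(max(abs(b$components %*% t(b$scores) - x)), 1e-8)
  expect_true(all(diff(b$singular_values) <= 1e-12))
  # eigenvectors of the region-space covariance span the same directions
  ev <- eigen(tcrossprod(x), symmetric = TRUE)$vectors[, 1:10]
  overlap <- abs(colSums(ev * b$components[, 1:10]))
  expect_true(all(overlap > 1 - 1e-6))     # principal angles ~ 0
  # rank-1 input: first component recovers the generating vector
  v0 <- corthick:::with_seed(4, {v <- rnorm(68); v / sqrt(sum(v^2))})
  w0 <- corthick:::with_seed(5, rnorm(40))
  b1 <- thickness_pca(v0 %*% t(w0))
  expect_equal(ncol(b1$components), 1)
  expect_lt(min(sum((b1$components[, 1] - v0)^2),
                sum((b1$components[, 1] + v0)^2)), 1e-16)
})

test_that("hat-matrix PRESS equals explicit leave-one-out refitting", {
  corthick:::with_seed(6, {
    for (i in 1:5) {
      n <- 40
      x <- remove_grand_mean_pattern(matrix(rnorm(68 * n, 2.5, 0.2), 68, n))
      b <- thickness_pca(x)
      dv <- rnorm(n)
      sel <- select_k_press(b, dv, k_max = 8)
      refit <- vapply(1:8, function(k) {
        Z <- cbind(1, b$scores[, 1:k, drop = FALSE])
        mean(vapply(1:n, function(j) {
          beta <- qr.coef(qr(Z[-j, , drop = FALSE]), dv[-j])
          (dv[j] - sum(Z[j, ] * beta))^2
        }, numeric(1)))
      }, numeric(1))
      expect_lt(max(abs(sel$press - refit)), 1e-10)
      expect_identical(sel$K, which.min(refit))
    }
  })
})

test_that("PRESS selection picks K = 1 for a noiseless PC1 relation and stays small under pure noise", {
  x <- corthick:::with_seed(7, {
    remove_grand_mean_pattern(matrix(rnorm(68 * 60, 2.5, 0.2), 68, 60))
  })
  b <- thickness_pca(x)
  expect_identical(select_k_press(b, 0.3 * b$scores[, 1], k_max = 10)$K, 1L)
  ks <- corthick:::with_seed(8, {
    vapply(1:100, function(i) {
      xi <- remove_grand_mean_pattern(matrix(rnorm(68 * 353, 2.5, 0.2), 68))
      select_k_press(thickness_pca(xi), rnorm(353), k_max = 15)$K
    }, integer(1))
  })
  expect_gte(mean(ks <= 2), 0.8)
  expect_error(select_k_press(b, rnorm(60), k_max = 58), "below n - 2")
})

test_that("derived patterns are unit norm with scores matching the projection", {
  x <- corthick:::with_seed(9, {
    remove_grand_mean_pattern(matrix(rnorm(68 * 50, 2.5, 0.2), 68, 50))
  })
  b <- thickness_pca(x)
  dv <- corthick:::with_seed(10, rnorm(50))
  for (K in c(1, 3, 7)) {
    pat <- derive_pattern(b, dv, K)
    expect_equal(sum(pat$loadings^2), 1, tolerance = 1e-12)
    expect_equal(pat$subject_scores, as.vector(t(x) %*% pat$loadings),
                 tolerance = 1e-10)
  }
  p1 <- derive_pattern(b, dv, 1)
  expect_lt(min(sum((p1$loadings - b$components[, 1])^2),
                sum((p1$loadings + b$components[, 1])^2)), 1e-20)
  expect_equal(abs(p1$fit_R), abs(cor(b$scores[, 1], dv)), tolerance = 1e-12)
  expect_equal(p1$fit_p,
               cor.test(p1$subject_scores, dv)$p.value, tolerance = 1e-8)
})

test_that("pattern decomposition reconstructs the data exactly", {
  x <- corthick:::with_seed(11, {
    remove_grand_mean_pattern(matrix(rnorm(68 * 30, 2.5, 0.2), 68, 30))
  })
  b <- thickness_pca(x)
  pat <- derive_pattern(b, corthick:::with_seed(12, rnorm(30)), 3)
  ress <- residual_signal(x, pat)
  E <- x - pat$loadings %*% t(pat$subject_scores)
  expect_equal(ress, colMeans(E^2), tolerance = 1e-12)
  expect_true(all(ress >= 0))
  # rank-1 data equal to v w': residuals vanish
  x1 <- pat$loadings %*% t(pat$subject_scores)
  b1 <- thickness_pca(x1)
  p1 <- derive_pattern(b1, pat$subject_scores, 1)
  expect_lt(max(residual_signal(x1, p1)), 1e-16)
  # pattern orthogonal to the subject profiles removes nothing
  v_orth <- qr.Q(qr(x), complete = TRUE)[, 68]
  fake <- structure(list(loadings = v_orth,
                         subject_scores = as.vector(t(x) %*% v_orth)),
                    class = "pattern_result")
  expect_lt(max(abs(fake$subject_scores)), 1e-10)
  expect_equal(residual_signal(x, fake), colMeans(x^2), tolerance = 1e-12)
})

test_that("bootstrap intervals are ordered, sign-stable and tight without noise", {
  v0 <- default_true_pattern()
  w0 <- corthick:::with_seed(13, rnorm(80))
  x <- v0 %*% t(w0)                       # noiseless rank-1 data
  bl <- bootstrap_loadings(x, w0, K = 1, n_boot = 120, seed = 14)
  expect_true(all(bl$lower <= bl$upper))
  nz <- abs(v0) > 1e-8
  expect_true(all(bl$robust[nz]))
  expect_lt(max(abs(bl$loading - v0)), 1e-10)
  expect_lt(max(bl$upper - bl$lower), 1e-10)
})

test_that("the adjusted pattern chain honours its invariants end to end", {
  cfg <- sim_config(n_subjects = 120, seed = 15)
  s <- generate_subjects(cfg)
  g <- generate_thickness(s, cfg)
  cov <- standardize_covariates(s)
  res <- ssm_pattern(g$thickness, cov, n_boot = 150, seed = 16)
  # adjustment guarantee: scores orthogonal to every confounder
  conf <- unclass(cov)[, res$confounders]
  expect_lt(max(abs(cor(res$pattern$subject_scores, conf))), 1e-8)
  expect_equal(sum(res$pattern$loadings^2), 1, tolerance = 1e-12)
  # decomposition identity: v w' + E reconstructs the residualized data
  E <- res$r_thx - res$pattern$loadings %*% t(res$pattern$subject_scores)
  expect_equal(res$ress, colMeans(E^2), tolerance = 1e-12)
  # scale invariance: thickness in different units, same pattern and fit
  thx2 <- suppressWarnings(
    thickness_matrix(unclass(g$thickness) * 2, dk_regions(), s$subject_id))
  suppressWarnings(res2 <- ssm_pattern(thx2, cov))
  expect_equal(abs(res2$pattern$fit_R), abs(res$pattern$fit_R),
               tolerance = 1e-8)
  expect_lt(min(max(abs(res2$pattern$loadings - res$pattern$loadings)),
                max(abs(res2$pattern$loadings + res$pattern$loadings))),
            1e-8)
  # swapping the dependent variable runs the identical code path
  res_cog <- ssm_pattern(g$thickness, cov, dv = "cognition")
  expect_setequal(res_cog$confounders,
                  c("education", "gender", "rfd", "age"))
})

test_that("RESS regression is calibrated under the null and detects planted heteroscedasticity", {
  ps <- t(vapply(1:30, function(seed) {
    cfg <- null_sim_config(seed, n_subjects = 100)
    s <- generate_subjects(cfg)
    g <- generate_thickness(s, cfg)
    cov <- standardize_covariates(s)
    res <- ssm_pattern(g$thickness, cov)
    res$ress_stats$p
  }, numeric(5)))
  band <- binom_band(length(ps))
  expect_gte(mean(ps < 0.05), band[1])
  expect_lte(mean(ps < 0.05), band[2])
  hits <- vapply(1:10, function(seed) {
    cfg <- sim_config(n_subjects = 353, seed = seed, age_hetero_slope = 0.03)
    s <- generate_subjects(cfg)
    g <- generate_thickness(s, cfg)
    res <- ssm_pattern(g$thickness, standardize_covariates(s))
    row <- res$ress_stats[res$ress_stats$covariate == "age", ]
    row$t > 0 && row$p < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})
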