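test_that("subject table round-trips through CSV bit-for-bit", {
  df <- validate_subject_table(make_subject_df(7))
  path <- withr::local_tempfile(fileext = ".csv")
  write_subject_table(df, path)
  back <- load_subject_table(path)
  for (col in c("age", "gender", "education", "rfd", "total_cognition"))
    expect_identical(back[[col]], df[[col]], label = col)
  expect_identical(back$subject_id, df$subject_id)
})

test_that("subject reader maps aliases, recodes gender strings, drops incomplete rows", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("ID,Age,Sex,EDU,rfd,cognition",
               "a,50,F,16,0.1,0.3",
               "b,60,M,12,0.2,-0.1",
               "c,70,F,,0.3,0.0"), path)
  expect_warning(
    tab <- load_subject_table(path, column_map = c(EDU = "education")),
    "dropped")
  expect_equal(nrow(tab), 2)
  expect_equal(tab$gender, c(2, 1))   # F = 2 (women), M = 1 (men)
  expect_equal(tab$education, c(16, 12))
})

test_that("invalid gender coding is rejected with row numbers", {
  df <- make_subject_df(4)
  df$gender[3] <- 7
  expect_error(validate_subject_table(df), "gender.*3")
})

test_that("composite cognition equals independent recomputation of 12 z-columns", {
  raw <- make_cognitive_raw(6)
  res <- compute_total_cognition(raw)
  # independent oracle: z-score each column by hand, reverse the time score
  z <- sapply(names(raw), function(t) {
    zz <- (raw[[t]] - mean(raw[[t]])) / sd(raw[[t]])
    if (t == "TrailsA-time") -zz else zz
  })
  expect_lt(max(abs(res$total_cognition - rowMeans(z))), 1e-12)
  dom <- cognitive_tests()
  for (d in names(dom))
    expect_lt(max(abs(res[[d]] - rowMeans(z[, dom[[d]]]))), 1e-12)
})

test_that("cognition composite behaves at the edges", {
  raw <- make_cognitive_raw(2)
  res <- compute_total_cognition(raw)
  # two subjects: z-scores are +/- the same magnitude, composite mean 0
  expect_equal(res$total_cognition[1], -res$total_cognition[2])
  expect_equal(mean(res$total_cognition), 0)
  raw$WTAR <- 50
  expect_error(compute_total_cognition(raw), "WTAR")
})

test_that("domain-mean composite differs from test-mean composite as documented", {
  raw <- make_cognitive_raw(8, seed = 9)
  a <- compute_total_cognition(raw, composite = "tests")$total_cognition
  b <- compute_total_cognition(raw, composite = "domains")$total_cognition
  # equal-weight domains of 3 tests each: the two composites coincide
  expect_equal(a, b, tolerance = 1e-12)
})

test_that("rFD aggregates as mean over runs of within-run means", {
  expect_equal(aggregate_rfd(list(list(c(0.1, 0.3), 0.5))), 0.35)
  expect_equal(aggregate_rfd(list(list(c(0.2, 0.4, 0.6)))), 0.4)
  runs <- corthick:::with_seed(5, replicate(10, runif(sample(1:5, 1)),
                                            simplify = FALSE))
  expect_equal(aggregate_rfd(list(runs)),
               mean(vapply(runs, mean, numeric(1))))
  expect_error(aggregate_rfd(list(list(numeric(0)))), "empty run")
})

test_that("standardize_covariates yields exact Z-columns in requested order", {
  df <- validate_subject_table(make_subject_df(15))
  m <- standardize_covariates(df, c("age", "gender", "education"))
  expect_identical(colnames(m), c("age", "gender", "education"))
  expect_true(all(abs(colMeans(m)) < 1e-10))
  expect_true(all(abs(apply(m, 2, sd) - 1) < 1e-10))
  # independent recomputation
  expect_equal(m[, "age"], (df$age - mean(df$age)) / sd(df$age),
               ignore_attr = TRUE)
  # two subjects: symmetric +/- 1/sqrt(2) under the sample-SD convention
  m2 <- standardize_covariates(validate_subject_table(make_subject_df(2)),
                               "age")
  expect_equal(sort(as.vector(m2)), c(-1, 1) / sqrt(2))
  df$age <- 50
  expect_error(standardize_covariates(df, "age"), "zero variance")
})

test_that("partial correlations match the residual-correlation oracle", {
  for (seed in c(1, 2, 3)) {
    df <- validate_subject_table(make_subject_df(40, seed = seed))
    cc <- covariate_correlations(df)
    vars <- c("education", "cognition", "gender", "rfd", "age")
    x <- standardize_covariates(df, vars)
    for (i in 1:4) for (j in (i + 1):5) {
      others <- x[, -c(i, j), drop = FALSE]
      ra <- residuals(lm(x[, i] ~ others))
      rb <- residuals(lm(x[, j] ~ others))
      expect_lt(abs(cc$partial[i, j] - cor(ra, rb)), 1e-10)
    }
    expect_equal(cc$bivariate, cor(x), ignore_attr = TRUE)
    # combined table: lower triangle bivariate, upper triangle partial
    expect_equal(cc$combined[2, 1], cc$bivariate[2, 1])
    expect_equal(cc$combined[1, 2], cc$partial[1, 2])
  }
})

test_that("independent covariates show near-zero correlations at large n", {
  df <- corthick:::with_seed(11, data.frame(
    subject_id = as.character(1:10000),
    age = runif(10000, 40, 80), gender = sample(1:2, 10000, TRUE),
    education = rnorm(10000, 16, 2), rfd = runif(10000, 0.05, 0.3),
    total_cognition = rnorm(10000)))
  cc <- covariate_correlations(validate_subject_table(df))
  off <- cc$combined[upper.tri(cc$combined) | lower.tri(cc$combined)]
  expect_true(all(abs(off) < 0.05))
})

test_that("thickness readers agree across dialects and round-trip exactly", {
  thx <- make_thickness(5)
  wide <- withr::local_tempfile(fileext = ".csv")
  write_thickness(thx, wide, sidecar = FALSE)
  t_wide <- load_thickness(wide, "wide_csv")
  expect_identical(unclass(t_wide), unclass(thx))

  # long dialect of the same numbers
  long <- withr::local_tempfile(fileext = ".csv")
  df <- data.frame(subject_id = rep(colnames(thx), each = 68),
                   region = rep(rownames(thx), times = ncol(thx)),
                   thickness = sprintf("%.17g", as.vector(unclass(thx))))
  write.csv(df, long, row.names = FALSE)
  t_long <- load_thickness(long, "long_csv")
  expect_equal(unclass(t_long), unclass(thx))

  # FreeSurfer aparc convention: split hemispheres, _thickness suffixes,
  # underscore separators, extra non-ROI columns
  lh <- withr::local_tempfile(fileext = ".txt"); rh <- withr::local_tempfile(fileext = ".txt")
  write_aparc <- function(path, hemi) {
    rows <- grepl(paste0("^", hemi, "-"), rownames(thx))
    m <- t(unclass(thx)[rows, , drop = FALSE])
    colnames(m) <- paste0(sub("-", "_", colnames(m)), "_thickness")
    df <- data.frame(check.names = FALSE,
                     stats::setNames(list(rownames(m)),
                                     paste0(hemi, ".aparc.thickness")))
    df <- cbind(df, as.data.frame(apply(m, 2, sprintf, fmt = "%.17g"),
                                  check.names = FALSE))
    df$eTIV <- 1500000
    write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  }
  write_aparc(lh, "lh"); write_aparc(rh, "rh")
  t_aparc <- load_thickness(c(lh, rh), "freesurfer_aparc_table")
  expect_equal(unclass(t_aparc), unclass(thx))
})

test_that("thickness validation catches wrong dimensions and bad values", {
  thx <- make_thickness(4)
  expect_error(thickness_matrix(unclass(thx)[-1, ], dk_regions()[-1],
                                colnames(thx)),
               "missing.*lh-bankssts")
  bad <- unclass(thx); bad[1, 1] <- -0.1
  expect_error(thickness_matrix(bad, dk_regions(), colnames(thx)),
               "non-positive")
  odd <- unclass(thx); odd[2, 1] <- 9
  expect_warning(thickness_matrix(odd, dk_regions(), colnames(thx)),
                 "plausible")
})
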