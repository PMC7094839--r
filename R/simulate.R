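#' Default covariate correlation targets
#'
#' The 5 x 5 correlation matrix used by the simulator for the latent
#' covariates (education, cognition, gender, rFD, age). Defaults are the
#' unadjusted bivariate correlations observed in the reference cohort of
#' 353 adults (education-cognition 0.32, cognition-age -0.23, etc.).
#'
#' @return Symmetric 5 x 5 matrix with unit diagonal.
#' @export
default_covariate_corr <- function() {
  vars <- c("education", "cognition", "gender", "rfd", "age")
  r <- diag(5)
  dimnames(r) <- list(vars, vars)
  lower <- c(
    cognition_education = 0.32,
    gender_education = -0.05, gender_cognition = -0.08,
    rfd_education = -0.07, rfd_cognition = -0.22, rfd_gender = 0.12,
    age_education = 0.12, age_cognition = -0.23, age_gender = 0.10,
    age_rfd = 0.12)
  for (nm in names(lower)) {
    ij <- strsplit(nm, "_")[[1]]
    r[ij[1], ij[2]] <- r[ij[2], ij[1]] <- lower[[nm]]
  }
  r
}

#' Default planted loading pattern
#'
#' Unit-L2-norm 68-region vector with dominant positive loadings on the
#' right isthmus and posterior cingulate, dominant negative loadings on the
#' right superior temporal gyrus and temporal pole, and small alternating
#' loadings elsewhere (mixed sign, near-zero sum so the pattern survives
#' grand-mean removal essentially intact).
#'
#' @return Named numeric vector of length 68 with unit L2 norm.
#' @export
default_true_pattern <- function() {
  regions <- dk_regions()
  v <- rep_len(c(0.03, -0.03), length(regions))
  names(v) <- regions
  v[c("rh-isthmuscingulate", "rh-posteriorcingulate")] <- c(0.55, 0.45)
  v[c("rh-superiortemporal", "rh-temporalpole")] <- c(-0.45, -0.55)
  v / sqrt(sum(v^2))
}

#' Simulation configuration
#'
#' Bundles the generator parameters with defaults matching the reference
#' cohort's scale: N = 353 subjects aged 40-80, education 16.3 +/- 2.4
#' years, mean cortical thickness around 2.57 mm, region-wise covariate
#' effects of a few hundredths of a millimetre per SD.
#'
#' @param n_subjects number of subjects.
#' @param target_corr 5 x 5 latent correlation matrix (education, cognition,
#'   gender, rfd, age); must be symmetric positive definite with unit
#'   diagonal.
#' @param baseline per-region mean thickness (mm), length 68.
#' @param region_effects 68 x 3 matrix of coefficients (mm per SD) for
#'   gender, rfd and age.
#' @param true_pattern unit-L2-norm 68-vector of planted pattern loadings.
#' @param pattern_strength education effect on pattern expression
#'   (mm per SD of education). The default, together with
#'   `pattern_expr_sd` and `noise_sd`, places the score-education
#'   correlation near 0.2.
#' @param pattern_expr_sd SD (mm) of subject-level pattern expression
#'   unrelated to education. This makes the planted pattern a covariance
#'   axis of the thickness data, as in real cortical data; set to 0 for a
#'   pattern expressed only through education.
#' @param noise_sd SD (mm) of independent region-level noise.
#' @param age_hetero_slope residual-SD multiplier per SD of age
#'   (SD = noise_sd * (1 + slope * z_age), floored at 5% of noise_sd);
#'   0 gives a homoscedastic cohort.
#' @param seed integer RNG seed.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_subjects = 353,
                       target_corr = default_covariate_corr(),
                       baseline = NULL,
                       region_effects = NULL,
                       true_pattern = default_true_pattern(),
                       pattern_strength = 0.055,
                       pattern_expr_sd = 0.25,
                       noise_sd = 0.1,
                       age_hetero_slope = 0,
                       seed = 1L) {
  p <- 68
  if (is.null(baseline)) {
    # deterministic spread 2.2-2.9 mm, cohort mean ~2.55
    baseline <- 2.2 + 0.7 * (seq_len(p) - 1) / (p - 1)
    names(baseline) <- dk_regions()
  }
  if (is.null(region_effects)) {
    idx <- (seq_len(p) - 1) / (p - 1)
    region_effects <- cbind(
      gender = 0.01 + 0.04 * idx,          # women thicker, up to 0.05 mm/SD
      rfd    = -(0.01 + 0.04 * rev(idx)),  # motion thins, up to -0.05 mm/SD
      age    = -(0.02 + 0.05 * idx))       # ageing thins, up to -0.07 mm/SD
    rownames(region_effects) <- dk_regions()
  }
  cfg <- list(n_subjects = n_subjects, target_corr = target_corr,
              baseline = baseline, region_effects = region_effects,
              true_pattern = true_pattern,
              pattern_strength = pattern_strength,
              pattern_expr_sd = pattern_expr_sd,
              noise_sd = noise_sd, age_hetero_slope = age_hetero_slope,
              seed = as.integer(seed))
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  r <- cfg$target_corr
  if (!isTRUE(all.equal(r, t(r))) || any(abs(diag(r) - 1) > 1e-12))
    stop("target_corr must be symmetric with unit diagonal", call. = FALSE)
  ch <- tryCatch(chol(r), error = function(e) NULL)
  if (is.null(ch))
    stop("target_corr is not positive definite", call. = FALSE)
  if (abs(sum(cfg$true_pattern^2) - 1) > 1e-8)
    stop("true_pattern must have unit L2 norm", call. = FALSE)
  if (length(cfg$true_pattern) != 68 || length(cfg$baseline) != 68 ||
      nrow(cfg$region_effects) != 68)
    stop("per-region parameters must have length 68", call. = FALSE)
  if (cfg$age_hetero_slope < 0) stop("age_hetero_slope must be >= 0")
  invisible(cfg)
}

#' Generate a synthetic subject table
#'
#' Draws latent multivariate-normal covariates with the configured
#' correlation structure, then maps them to observable scales: age uniform
#' on [40, 80] (via the latent normal CDF), education 16.3 +/- 2.4 years,
#' rFD lognormal around 0.15 (mild skew, as for motion summaries), total
#' cognition left on the composite-Z scale, and gender dichotomized at the
#' latent median (1 = men, 2 = women). Deterministic under `config$seed`.
#'
#' @param config a [sim_config()].
#' @param cognitive_raw also generate the 12 raw cognitive test scores
#'   consistent with the latent cognition (loading 0.7 per test, times
#'   sign-reversed where appropriate).
#' @return A `subject_table`.
#' @export
generate_subjects <- function(config, cognitive_raw = FALSE) {
  validate_sim_config(config)
  n <- config$n_subjects
  vars <- c("education", "cognition", "gender", "rfd", "age")
  z <- with_seed(stage_seed(config$seed, "simulate"), {
    lat <- matrix(stats::rnorm(n * 5), n, 5) %*% chol(config$target_corr)
    colnames(lat) <- vars
    df <- data.frame(
      subject_id = sprintf("sub-%04d", seq_len(n)),
      age = 40 + 40 * stats::pnorm(lat[, "age"]),
      gender = ifelse(lat[, "gender"] > stats::median(lat[, "gender"]), 2, 1),
      education = pmax(16.3 + 2.4 * lat[, "education"], 0),
      rfd = exp(log(0.15) + 0.4 * lat[, "rfd"]),
      total_cognition = lat[, "cognition"],
      stringsAsFactors = FALSE)
    if (cognitive_raw) {
      scales <- list(
        "SRTLTS" = c(48, 10), "SRT-CLRT" = c(40, 12), "SRT-Last" = c(9, 2),
        "DigitSymbol" = c(55, 14), "TrailsA-time" = c(35, 12),
        "StroopColor" = c(75, 12), "BlockDesign" = c(35, 10),
        "LetterNumber" = c(11, 3), "Ravens" = c(9, 3),
        "WAIS-Vocab" = c(45, 9), "WTAR" = c(41, 7), "AMNART" = c(120, 8))
      for (t in names(scales)) {
        lam <- 0.7
        latent <- lam * lat[, "cognition"] +
          sqrt(1 - lam^2) * stats::rnorm(n)
        if (t == "TrailsA-time") latent <- -latent
        df[[t]] <- scales[[t]][1] + scales[[t]][2] * latent
      }
    }
    df
  })
  validate_subject_table(z)
}

#' Generate a synthetic thickness matrix with known ground truth
#'
#' Thickness of region i in subject s is
#' `baseline_i + sum_c effects_ic * z_c(s) +
#'  pattern_i * (pattern_strength * z_edu(s) + pattern_expr_sd * eta_s) +
#'  eps_is`, with `eps_is ~ N(0, noise_sd * (1 + age_hetero_slope *
#' z_age(s)))` (SD floored at 5% of `noise_sd`). The returned ground-truth
#' record carries every planted quantity, including the per-subject pattern
#' expression.
#'
#' @param subjects a `subject_table` (typically from [generate_subjects()]).
#' @param config a [sim_config()].
#' @return List with `thickness` (a `thickness_matrix`) and `ground_truth`
#'   (list of planted parameters).
#' @export
generate_thickness <- function(subjects, config) {
  validate_sim_config(config)
  subjects <- validate_subject_table(subjects, require_cognition = TRUE)
  n <- nrow(subjects)
  z <- standardize_covariates(
    subjects, c("education", "gender", "cognition", "rfd", "age"))
  out <- with_seed(stage_seed(config$seed, "thickness"), {
    expr_noise <- stats::rnorm(n, 0, 1)
    expression <- config$pattern_strength * z[, "education"] +
      config$pattern_expr_sd * expr_noise
    sd_s <- config$noise_sd *
      pmax(1 + config$age_hetero_slope * z[, "age"], 0.05)
    eps <- matrix(stats::rnorm(68 * n), 68, n) *
      matrix(sd_s, 68, n, byrow = TRUE)
    vals <- matrix(config$baseline, 68, n) +
      config$region_effects %*% t(z[, c("gender", "rfd", "age")]) +
      config$true_pattern %*% t(expression) + eps
    list(vals = vals, expression = expression, noise_sd_subject = sd_s)
  })
  if (any(out$vals <= 0))
    stop("generated non-positive thickness; reduce effect sizes or noise",
         call. = FALSE)
  thx <- thickness_matrix(out$vals, dk_regions(), subjects$subject_id)
  list(thickness = thx,
       ground_truth = list(
         baseline = config$baseline,
         region_effects = config$region_effects,
         true_pattern = config$true_pattern,
         pattern_strength = config$pattern_strength,
         pattern_expr_sd = config$pattern_expr_sd,
         noise_sd = config$noise_sd,
         age_hetero_slope = config$age_hetero_slope,
         pattern_expression = out$expression,
         noise_sd_subject = out$noise_sd_subject,
         covariates_z = z,
         seed = config$seed))
}
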