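#' @title Subject tables: covariates and cognitive scores
#' @name subject_table
#' @description A `subject_table` is a data.frame with one row per subject
#'   and at least the columns `subject_id`, `age` (years), `gender`
#'   (1 = men, 2 = women), `education` (years), `rfd` (mean relative
#'   framewise displacement). A `total_cognition` composite Z and/or the 12
#'   raw cognitive test scores may be present.
NULL

#' Names of the 12 cognitive tests, by domain
#'
#' Three tests per domain: memory, speed, reasoning, vocabulary. Higher raw
#' scores mean better performance except for the Trail Making A completion
#' time, which is sign-reversed during Z-scoring.
#'
#' @return Named list of four character vectors of length 3.
#' @export
cognitive_tests <- function() {
  list(
    memory     = c("SRTLTS", "SRT-CLRT", "SRT-Last"),
    speed      = c("DigitSymbol", "TrailsA-time", "StroopColor"),
    reasoning  = c("BlockDesign", "LetterNumber", "Ravens"),
    vocabulary = c("WAIS-Vocab", "WTAR", "AMNART")
  )
}

required_covariates <- c("age", "gender", "education", "rfd")

new_subject_table <- function(df) {
  class(df) <- c("subject_table", "data.frame")
  df
}

#' Validate a subject table
#'
#' Checks uniqueness of `subject_id`, the 1/2 gender coding, and the absence
#' of missing values in the required covariates.
#'
#' @param df data.frame with subject columns.
#' @param require_cognition also require a `total_cognition` column.
#' @return The validated table, classed `subject_table`, invisibly usable
#'   downstream.
#' @export
validate_subject_table <- function(df, require_cognition = FALSE) {
  need <- c("subject_id", required_covariates)
  if (require_cognition) need <- c(need, "total_cognition")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("subject table lacks columns: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  if (anyDuplicated(df$subject_id))
    stop("duplicated subject_id values", call. = FALSE)
  bad <- which(!df$gender %in% c(1, 2))
  if (length(bad))
    stop("gender must be coded 1 (men) / 2 (women); offending rows: ",
         paste(utils::head(bad, 10), collapse = ", "), call. = FALSE)
  if (any(df$age <= 0, na.rm = TRUE)) stop("age must be positive")
  if (any(df$education < 0, na.rm = TRUE)) stop("education must be >= 0")
  if (any(df$rfd < 0, na.rm = TRUE)) stop("rfd must be >= 0")
  new_subject_table(df)
}

#' Read a subject table from CSV/TSV
#'
#' Column names are matched case-insensitively against the schema after
#' applying `column_map`; gender given as strings is recoded through
#' `gender_codes` (internal coding is fixed at 1 = men, 2 = women). Rows
#' with a missing required covariate are dropped with a warning giving the
#' count (complete-case policy).
#'
#' @param path file path.
#' @param format `"csv"` or `"tsv"`.
#' @param column_map named character vector mapping file column names to
#'   schema names, e.g. `c(EDU = "education")`.
#' @param gender_codes named numeric vector mapping string codes to 1/2;
#'   defaults cover M/F and male/female.
#' @return A `subject_table`.
#' @export
load_subject_table <- function(path, format = c("csv", "tsv"),
                               column_map = NULL,
                               gender_codes = c(M = 1, male = 1, men = 1,
                                                F = 2, female = 2, women = 2)) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- tryCatch(
    utils::read.table(path, header = TRUE,
                      sep = if (format == "csv") "," else "\t",
                      quote = "\"", check.names = FALSE,
                      stringsAsFactors = FALSE),
    error = function(e) stop("could not parse ", path, ": ",
                             conditionMessage(e), call. = FALSE))
  nm <- names(df)
  if (!is.null(column_map)) {
    hit <- match(nm, names(column_map))
    nm[!is.na(hit)] <- column_map[hit[!is.na(hit)]]
  }
  # case-insensitive aliases for the schema columns
  aliases <- c(subject_id = "subject_id", id = "subject_id",
               age = "age", gender = "gender", sex = "gender",
               education = "education", edu = "education",
               rfd = "rfd", total_cognition = "total_cognition",
               cognition = "total_cognition")
  low <- tolower(nm)
  hit <- match(low, names(aliases))
  nm[!is.na(hit)] <- aliases[hit[!is.na(hit)]]
  names(df) <- nm
  miss <- setdiff(c("subject_id", required_covariates), nm)
  if (length(miss)) stop("input lacks required columns: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  if (is.character(df$gender) || is.factor(df$gender)) {
    g <- as.character(df$gender)
    mapped <- gender_codes[g]
    numeric_ok <- suppressWarnings(as.numeric(g))
    df$gender <- ifelse(is.na(mapped), numeric_ok, mapped)
  }
  for (col in c("age", "gender", "education", "rfd", "total_cognition")) {
    if (col %in% names(df)) df[[col]] <- as.numeric(df[[col]])
  }
  keep <- stats::complete.cases(df[required_covariates])
  if (any(!keep)) {
    warning(sum(!keep), " row(s) dropped for missing required covariates",
            call. = FALSE)
    df <- df[keep, , drop = FALSE]
    rownames(df) <- NULL
  }
  df$subject_id <- as.character(df$subject_id)
  validate_subject_table(df)
}

#' Write a subject table to CSV at full precision
#'
#' Numeric columns are written with 17 significant digits so that a
#' write/read round trip reproduces the doubles bit-for-bit.
#'
#' @param table a `subject_table`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_subject_table <- function(table, path) {
  out <- as.data.frame(lapply(table, full_precision),
                       check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Composite and domain cognition scores from raw tests
#'
#' Each of the 12 tests is Z-scored across subjects (sample SD); completion
#' times (by default Trail Making A) are sign-reversed so that higher Z
#' always means better performance. Each domain score is the mean of its
#' three test Zs. The composite is either the mean of all 12 test Zs
#' (default) or the mean of the 4 domain scores — the two differ when test
#' variances differ within a domain, and the 12-test mean matches the
#' description of the composite as the average of all Z-scores.
#'
#' @param raw data.frame or matrix with the 12 test columns named as in
#'   [cognitive_tests()], one row per subject.
#' @param reverse character vector of tests whose raw scores decrease with
#'   better performance.
#' @param composite `"tests"` (mean of 12 test Zs) or `"domains"` (mean of
#'   the 4 domain means).
#' @return data.frame with `total_cognition` and one column per domain.
#' @export
compute_total_cognition <- function(raw, reverse = "TrailsA-time",
                                    composite = c("tests", "domains")) {
  composite <- match.arg(composite)
  domains <- cognitive_tests()
  tests <- unlist(domains, use.names = FALSE)
  raw <- as.data.frame(raw, check.names = FALSE)
  miss <- setdiff(tests, names(raw))
  if (length(miss)) stop("missing cognitive test columns: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  if (nrow(raw) < 2) stop("need at least 2 subjects to Z-score")
  if (anyNA(raw[tests])) stop("missing values in cognitive test scores")
  z <- sapply(tests, function(t) {
    x <- as.numeric(raw[[t]])
    s <- stats::sd(x)
    if (!is.finite(s) || s == 0)
      stop("zero variance in cognitive test '", t, "'", call. = FALSE)
    zz <- (x - mean(x)) / s
    if (t %in% reverse) -zz else zz
  })
  dom <- sapply(domains, function(cols) rowMeans(z[, cols, drop = FALSE]))
  total <- if (composite == "tests") rowMeans(z) else rowMeans(dom)
  data.frame(total_cognition = total, dom, check.names = FALSE)
}

#' Aggregate framewise displacement across volumes and runs
#'
#' Per subject: mean within each run across volumes, then mean across runs.
#' Runs are weighted equally regardless of their number of volumes.
#'
#' @param per_run_displacements list (one element per subject) of lists of
#'   numeric vectors (one per run) of per-volume relative framewise
#'   displacements.
#' @return Numeric vector, one mean rFD per subject.
#' @export
aggregate_rfd <- function(per_run_displacements) {
  vapply(per_run_displacements, function(runs) {
    if (!length(runs)) stop("subject with no runs", call. = FALSE)
    run_means <- vapply(runs, function(r) {
      if (!length(r)) stop("empty run", call. = FALSE)
      mean(as.numeric(r))
    }, numeric(1))
    mean(run_means)
  }, numeric(1))
}

#' Z-standardize covariates into a design block
#'
#' Columns are taken from the subject table in the requested order and
#' Z-scored with the sample SD (n - 1). Gender is Z-scored from its numeric
#' 1/2 coding. The result is a plain numeric matrix (subjects x p) with a
#' `"covariate_matrix"` class tag; no intercept column is included (fits add
#' one internally).
#'
#' @param table a `subject_table` (the `cognition` column name maps to
#'   `total_cognition`).
#' @param columns ordered covariate names, subset of
#'   `c("education", "gender", "cognition", "rfd", "age")`.
#' @return subjects x p matrix, columns named as requested.
#' @export
standardize_covariates <- function(table,
                                   columns = c("education", "gender",
                                               "cognition", "rfd", "age")) {
  src <- ifelse(columns == "cognition", "total_cognition", columns)
  miss <- setdiff(src, names(table))
  if (length(miss)) stop("subject table lacks columns: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  m <- sapply(seq_along(columns), function(j) {
    x <- as.numeric(table[[src[j]]])
    if (anyNA(x)) stop("missing values in covariate '", columns[j], "'")
    s <- stats::sd(x)
    if (!is.finite(s) || s == 0)
      stop("zero variance in covariate '", columns[j], "'", call. = FALSE)
    (x - mean(x)) / s
  })
  dimnames(m) <- list(table$subject_id, columns)
  class(m) <- c("covariate_matrix", class(m))
  m
}

#' Bivariate and partial correlations among the subject covariates
#'
#' Computes all pairwise Pearson correlations among education, cognition,
#' gender, rFD and age, and the partial correlation of each pair adjusting
#' for the remaining three variables, with two-sided p-values. The combined
#' matrix carries partial correlations in the upper triangle and unadjusted
#' bivariate correlations in the lower triangle.
#'
#' @param table a `subject_table` with a `total_cognition` column.
#' @return List with matrices `bivariate`, `partial`, `p_bivariate`,
#'   `p_partial`, `combined`, and `n`.
#' @export
covariate_correlations <- function(table) {
  vars <- c("education", "cognition", "gender", "rfd", "age")
  x <- standardize_covariates(table, vars)
  n <- nrow(x)
  if (n < 7) stop("need at least 7 subjects for partial correlations")
  r <- stats::cor(x)
  # partials via the precision matrix: adjusts each pair for the other 3
  prec <- tryCatch(solve(r), error = function(e)
    stop("singular covariate correlation matrix", call. = FALSE))
  d <- 1 / sqrt(diag(prec))
  pr <- -prec * outer(d, d)
  diag(pr) <- 1
  p_of <- function(rr, df) {
    t <- rr * sqrt(df / pmax(1 - rr^2, .Machine$double.eps))
    2 * stats::pt(-abs(t), df)
  }
  p_biv <- p_of(r, n - 2)
  p_par <- p_of(pr, n - 2 - (length(vars) - 2))
  diag(p_biv) <- diag(p_par) <- NA_real_
  comb <- r
  comb[upper.tri(comb)] <- pr[upper.tri(pr)]
  diag(comb) <- NA_real_
  list(bivariate = r, partial = pr, p_bivariate = p_biv,
       p_partial = p_par, combined = comb, n = n)
}
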