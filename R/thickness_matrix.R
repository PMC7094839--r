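#' @title Thickness matrices
#' @name thickness_matrix
#' @description A `thickness_matrix` holds mean cortical thickness (mm) for
#'   the 68 Desikan-Killiany regions: a regions x subjects numeric matrix
#'   with canonical region order (see [dk_regions()]) and subject ids as
#'   column names. Subject order must match the paired `subject_table`.
NULL

#' Construct and validate a thickness matrix
#'
#' @param values regions x subjects numeric matrix.
#' @param region_labels 68 region labels (any resolvable spelling).
#' @param subject_ids subject identifiers, one per column.
#' @return A `thickness_matrix` (matrix with class tag), rows reordered to
#'   the canonical region order.
#' @export
thickness_matrix <- function(values, region_labels = rownames(values),
                             subject_ids = colnames(values)) {
  values <- as.matrix(values)
  if (is.null(region_labels)) stop("region labels required")
  if (length(region_labels) != nrow(values))
    stop("region_labels length must match rows")
  norm <- resolve_regions(region_labels)
  canon <- dk_regions()
  values <- values[match(canon, norm), , drop = FALSE]
  rownames(values) <- canon
  if (is.null(subject_ids)) subject_ids <- as.character(seq_len(ncol(values)))
  colnames(values) <- as.character(subject_ids)
  if (anyNA(values)) stop("missing thickness values", call. = FALSE)
  if (any(values <= 0))
    stop("non-positive thickness values present", call. = FALSE)
  if (any(values < 0.5 | values > 6))
    warning("thickness values outside the plausible (0.5, 6.0) mm range",
            call. = FALSE)
  class(values) <- c("thickness_matrix", class(values))
  values
}

#' Read a thickness table
#'
#' Three dialects are supported:
#' \describe{
#'   \item{`wide_csv`}{first column subject id, 68 region columns.}
#'   \item{`long_csv`}{columns `subject_id`, `region`, `thickness`.}
#'   \item{`freesurfer_aparc_table`}{the tab-separated subjects x regions
#'     export convention, headers like `lh_bankssts_thickness`; pass the
#'     left- and right-hemisphere files as a length-2 `path` (they are
#'     merged on subject id). Non-ROI columns (`MeanThickness`, `eTIV`,
#'     `BrainSegVolNotVent`, ...) are ignored.}
#' }
#'
#' @param path file path (length 2 for split aparc tables).
#' @param dialect one of `"wide_csv"`, `"long_csv"`,
#'   `"freesurfer_aparc_table"`.
#' @return A `thickness_matrix` in canonical region order.
#' @export
load_thickness <- function(path, dialect = c("wide_csv", "long_csv",
                                             "freesurfer_aparc_table")) {
  dialect <- match.arg(dialect)
  for (p in path) if (!file.exists(p)) stop("file not found: ", p)
  if (dialect == "wide_csv") {
    df <- utils::read.csv(path[1], check.names = FALSE,
                          stringsAsFactors = FALSE)
    ids <- as.character(df[[1]])
    vals <- t(as.matrix(df[, -1, drop = FALSE]))
    return(thickness_matrix(vals, rownames(vals), ids))
  }
  if (dialect == "long_csv") {
    df <- utils::read.csv(path[1], check.names = FALSE,
                          stringsAsFactors = FALSE)
    need <- c("subject_id", "region", "thickness")
    if (!all(need %in% names(df)))
      stop("long_csv needs columns: ", paste(need, collapse = ", "))
    df$region <- normalize_region_labels(df$region)
    ids <- unique(df$subject_id)
    regions <- unique(df$region)
    vals <- matrix(NA_real_, length(regions), length(ids),
                   dimnames = list(regions, ids))
    vals[cbind(match(df$region, regions), match(df$subject_id, ids))] <-
      df$thickness
    return(thickness_matrix(vals, regions, ids))
  }
  # freesurfer_aparc_table: one or two tab-separated files, merged on id
  parts <- lapply(path, function(p) {
    df <- utils::read.delim(p, check.names = FALSE, stringsAsFactors = FALSE)
    ids <- as.character(df[[1]])
    df <- df[, -1, drop = FALSE]
    labs <- normalize_region_labels(names(df))
    keep <- labs %in% dk_regions()
    df <- df[, keep, drop = FALSE]
    names(df) <- labs[keep]
    rownames(df) <- ids
    df
  })
  merged <- parts[[1]]
  if (length(parts) > 1) {
    for (p in parts[-1]) {
      if (!identical(sort(rownames(merged)), sort(rownames(p))))
        stop("aparc tables list different subjects", call. = FALSE)
      merged <- cbind(merged, p[rownames(merged), , drop = FALSE])
    }
  }
  thickness_matrix(t(as.matrix(merged)), colnames(merged), rownames(merged))
}

#' Write a thickness matrix as canonical wide CSV
#'
#' One row per subject, first column `subject_id`, 68 region columns in
#' canonical order, 17 significant digits (bit-exact round trip). A JSON
#' sidecar (`<path>.json`) records region order and dimensions.
#'
#' @param thx a `thickness_matrix`.
#' @param path output CSV path.
#' @param sidecar write the JSON metadata sidecar.
#' @return `path`, invisibly.
#' @export
write_thickness <- function(thx, path, sidecar = TRUE) {
  df <- data.frame(subject_id = colnames(thx), check.names = FALSE,
                   stringsAsFactors = FALSE)
  for (r in rownames(thx)) df[[r]] <- full_precision(thx[r, ])
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  if (sidecar) {
    jsonlite::write_json(
      list(n_regions = nrow(thx), n_subjects = ncol(thx),
           region_order = rownames(thx), subject_ids = colnames(thx)),
      paste0(path, ".json"), auto_unbox = TRUE)
  }
  invisible(path)
}
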