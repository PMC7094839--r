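#' Canonical Desikan-Killiany region labels
#'
#' The 68 cortical regions of the Desikan-Killiany parcellation (34 per
#' hemisphere), in the package's canonical order: alphabetical within
#' hemisphere, left-hemisphere block first. All region-indexed vectors and
#' matrices in this package use this order.
#'
#' @return Character vector of 68 labels, e.g. `"lh-bankssts"`,
#'   `"rh-isthmuscingulate"`.
#' @export
dk_regions <- function() {
  base <- sort(c(
    "bankssts", "caudalanteriorcingulate", "caudalmiddlefrontal", "cuneus",
    "entorhinal", "frontalpole", "fusiform", "inferiorparietal",
    "inferiortemporal", "insula", "isthmuscingulate", "lateraloccipital",
    "lateralorbitofrontal", "lingual", "medialorbitofrontal",
    "middletemporal", "paracentral", "parahippocampal", "parsopercularis",
    "parsorbitalis", "parstriangularis", "pericalcarine", "postcentral",
    "posteriorcingulate", "precentral", "precuneus",
    "rostralanteriorcingulate", "rostralmiddlefrontal", "superiorfrontal",
    "superiorparietal", "superiortemporal", "supramarginal", "temporalpole",
    "transversetemporal"
  ))
  c(paste0("lh-", base), paste0("rh-", base))
}

#' Normalize region labels to canonical form
#'
#' Accepts FreeSurfer-style labels (`"lh_bankssts_thickness"`,
#' `"lh_bankssts"`) and canonical labels (`"lh-bankssts"`); strips a
#' trailing `"_thickness"` suffix and rewrites the hemisphere separator.
#'
#' @param labels character vector of region labels.
#' @return Character vector of normalized labels (not reordered).
#' @export
normalize_region_labels <- function(labels) {
  x <- sub("_thickness$", "", labels)
  x <- sub("^(lh|rh)[_.]", "\\1-", x)
  x
}

# Match labels against the canonical 68; error with the offending names.
resolve_regions <- function(labels) {
  canon <- dk_regions()
  norm <- normalize_region_labels(labels)
  missing <- setdiff(canon, norm)
  extra <- setdiff(norm, canon)
  if (length(missing) || length(extra)) {
    stop("expected the 68 Desikan-Killiany regions; missing: [",
         paste(missing, collapse = ", "), "]; unrecognized: [",
         paste(extra, collapse = ", "), "]", call. = FALSE)
  }
  if (anyDuplicated(norm)) {
    stop("duplicated region labels: ",
         paste(unique(norm[duplicated(norm)]), collapse = ", "),
         call. = FALSE)
  }
  norm
}
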