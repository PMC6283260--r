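#' @keywords internal
FEATURE_CLASSES <- c(
  "plasma", "hallmark", "demographic",
  "brain_thickness", "brain_area", "brain_volume",
  "corex_plasma", "corex_brain"
)

#' Subject-by-feature table with per-feature class tags
#'
#' The central data container of the package: a numeric subjects x features
#' matrix in which every feature carries exactly one class tag identifying the
#' panel it belongs to (plasma analyte, CSF/genetic hallmark, demographic,
#' one of the three structural brain measure types, or a learned latent
#' factor label column).
#'
#' @param x Numeric matrix (or data.frame coercible to one) with subject IDs
#'   as rownames and feature names as colnames.
#' @param classes Character vector of class tags, one per feature, either
#'   named by feature or in column order. Valid tags: `plasma`, `hallmark`,
#'   `demographic`, `brain_thickness`, `brain_area`, `brain_volume`,
#'   `corex_plasma`, `corex_brain`.
#' @return An object of class `feature_table` with elements `data` (numeric
#'   matrix) and `classes` (named character vector aligned to columns).
#' @export
feature_table <- function(x, classes) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (is.null(colnames(x))) stop("feature_table requires feature names as colnames")
  if (is.null(rownames(x))) rownames(x) <- sprintf("S%04d", seq_len(nrow(x)))
  if (anyDuplicated(colnames(x))) stop("duplicate feature names")
  if (is.null(names(classes))) {
    if (length(classes) != ncol(x)) stop("classes must have one tag per feature")
    names(classes) <- colnames(x)
  }
  classes <- classes[colnames(x)]
  if (anyNA(classes)) {
    stop("missing class tag for feature(s): ",
         paste(colnames(x)[is.na(classes)], collapse = ", "))
  }
  bad <- setdiff(unique(classes), FEATURE_CLASSES)
  if (length(bad)) {
    stop("unknown feature class tag(s): ", paste(bad, collapse = ", "))
  }
  structure(list(data = x, classes = classes), class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("<feature_table> %d subjects x %d features\n",
              nrow(x$data), ncol(x$data)))
  tab <- table(x$classes)
  cat(paste(sprintf("  %s: %d", names(tab), tab), collapse = "\n"), "\n")
  invisible(x)
}

#' @export
dim.feature_table <- function(x) dim(x$data)

#' Extract the numeric matrix of a feature table
#' @param ft A `feature_table`.
#' @return Numeric matrix.
#' @export
ft_data <- function(ft) ft$data

#' Per-feature class tags
#' @param ft A `feature_table`.
#' @return Named character vector.
#' @export
ft_classes <- function(ft) ft$classes

#' Subject identifiers
#' @param ft A `feature_table`.
#' @return Character vector of subject IDs (rownames).
#' @export
ft_subjects <- function(ft) rownames(ft$data)

#' Subset a feature table by class tag and/or feature name
#'
#' @param ft A `feature_table`.
#' @param tags Optional character vector of class tags to keep.
#' @param features Optional character vector of feature names to keep.
#' @param subjects Optional vector of subject IDs or row indices to keep.
#' @return A `feature_table`.
#' @export
ft_select <- function(ft, tags = NULL, features = NULL, subjects = NULL) {
  keep <- colnames(ft$data)
  if (!is.null(tags)) keep <- keep[ft$classes[keep] %in% tags]
  if (!is.null(features)) {
    missing <- setdiff(features, keep)
    if (length(missing)) stop("unknown feature(s): ", paste(missing, collapse = ", "))
    keep <- keep[keep %in% features]
  }
  rows <- if (is.null(subjects)) seq_len(nrow(ft$data)) else subjects
  feature_table(ft$data[rows, keep, drop = FALSE], ft$classes[keep])
}

#' Bind feature tables column-wise over the same subjects
#'
#' @param ... Two or more `feature_table` objects sharing subject IDs in the
#'   same order.
#' @return A single `feature_table`.
#' @export
ft_cbind <- function(...) {
  fts <- list(...)
  ids <- lapply(fts, ft_subjects)
  if (!all(vapply(ids, identical, logical(1), y = ids[[1]]))) {
    stop("feature tables must share identical subject IDs in the same order")
  }
  feature_table(do.call(cbind, lapply(fts, ft_data)),
                do.call(c, lapply(fts, ft_classes)))
}

#' Map fine-grained class tags onto the four selection classes
#'
#' Feature ranking and top-k selection operate on four coarse classes:
#' original plasma-side measures (plasma + hallmark + demographic), original
#' brain measures (thickness + area + volume), latent plasma factors and
#' latent brain factors.
#'
#' @param tags Character vector of `feature_table` class tags.
#' @return Character vector over `plasma`, `brain`, `corex_plasma`,
#'   `corex_brain`.
#' @export
selection_class <- function(tags) {
  out <- rep(NA_character_, length(tags))
  out[tags %in% c("plasma", "hallmark", "demographic")] <- "plasma"
  out[tags %in% c("brain_thickness", "brain_area", "brain_volume")] <- "brain"
  out[tags == "corex_plasma"] <- "corex_plasma"
  out[tags == "corex_brain"] <- "corex_brain"
  if (anyNA(out)) stop("unknown class tag(s)")
  names(out) <- names(tags)
  out
}
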