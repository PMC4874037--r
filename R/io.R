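#' Omics matrices and class labels
#'
#' An `omics_matrix` is a plain numeric feature x sample matrix carrying a
#' `layer` tag (`"gene"` or `"metabolite"`); missing values are `NA`. Class
#' labels are a named integer vector mapping sample ids to classes 1 and 2,
#' with display names kept as an attribute.
#'
#' @param values numeric matrix with unique rownames (features) and unique
#'   colnames (samples).
#' @param layer `"gene"` or `"metabolite"`.
#' @return `omics_matrix()` returns the matrix with class `omics_matrix` and
#'   a `layer` attribute.
#' @export
omics_matrix <- function(values, layer = c("gene", "metabolite")) {
  layer <- match.arg(layer)
  if (!is.matrix(values) || !is.numeric(values))
    fail("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    fail("`values` must have feature rownames and sample colnames")
  dup <- rownames(values)[duplicated(rownames(values))]
  if (length(dup))
    fail("duplicate feature id(s): %s", paste(unique(dup), collapse = ", "))
  dup <- colnames(values)[duplicated(colnames(values))]
  if (length(dup))
    fail("duplicate sample id(s): %s", paste(unique(dup), collapse = ", "))
  structure(values, layer = layer, class = c("omics_matrix", class(values)))
}

#' @rdname omics_matrix
#' @param classes named integer vector (values 1 or 2; names are sample ids).
#' @param class_names length-2 character vector of display names for classes
#'   1 and 2.
#' @export
class_labels <- function(classes, class_names = c("class1", "class2")) {
  ids <- names(classes)
  if (is.null(ids) || anyDuplicated(ids))
    fail("`classes` must be named by unique sample ids")
  classes <- as.integer(classes)
  if (!all(classes %in% c(1L, 2L)))
    fail("classes must be coded 1 or 2")
  if (!all(c(1L, 2L) %in% classes))
    fail("both classes must be non-empty")
  structure(classes, names = ids, class_names = class_names,
            class = "class_labels")
}

# Match labels to the columns of a matrix; returns an integer vector of
# classes in column order.  Requires >= 2 samples per class.
align_labels <- function(mat, labels) {
  missing <- setdiff(colnames(mat), names(labels))
  if (length(missing))
    fail("samples without labels: %s", paste(missing, collapse = ", "))
  cls <- unclass(labels)[colnames(mat)]
  if (sum(cls == 1L) < 2L || sum(cls == 2L) < 2L)
    fail("need at least 2 samples per class, got %d / %d",
         sum(cls == 1L), sum(cls == 2L))
  unname(cls)
}

#' Read and write omics matrices
#'
#' TSV layout: first column holds feature ids (header `feature_id`), the
#' remaining header fields are sample ids. Empty cells and `"NA"`
#' (case-insensitive) are read as missing; missing values are written as
#' empty cells.
#'
#' @param path file path.
#' @param layer `"gene"` or `"metabolite"`.
#' @return `read_omics_matrix()` returns an [omics_matrix()].
#' @export
read_omics_matrix <- function(path, layer = c("gene", "metabolite")) {
  layer <- match.arg(layer)
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   na.strings = c("", "NA", "na", "Na", "nA"),
                   colClasses = NA, fill = FALSE,
                   stringsAsFactors = FALSE)
  if (ncol(df) < 2L) fail("%s: expected a feature id column plus samples", path)
  ids <- as.character(df[[1L]])
  dup <- ids[duplicated(ids)]
  if (length(dup))
    fail("%s: duplicate feature id(s): %s", path,
         paste(unique(dup), collapse = ", "))
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  omics_matrix(m, layer)
}

#' @rdname read_omics_matrix
#' @param mat an [omics_matrix()] (or numeric matrix with dimnames).
#' @export
write_omics_matrix <- function(mat, path) {
  df <- data.frame(feature_id = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_tsv(df, path)
}

#' Read and write sample class labels
#'
#' TSV with header `sample_id<TAB>class`; class is 1 or 2.
#' @param path file path.
#' @inheritParams class_labels
#' @export
read_labels <- function(path, class_names = c("class1", "class2")) {
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE, fill = FALSE)
  if (!all(c("sample_id", "class") %in% names(df)))
    fail("%s: expected columns sample_id and class", path)
  class_labels(structure(df$class, names = df$sample_id), class_names)
}

#' @rdname read_labels
#' @param labels a [class_labels()] vector.
#' @export
write_labels <- function(labels, path) {
  write_tsv(data.frame(sample_id = names(labels), class = unclass(labels)),
            path)
}

#' Filter, impute and normalize an omics matrix
#'
#' Features whose missing fraction exceeds `max_missing_frac` are removed.
#' Remaining missing entries are imputed per feature: half the observed
#' minimum for metabolites (the field convention for left-censored LC-MS
#' intensities) and the observed median for genes. If `log_transform`, values
#' are then replaced by `log2(value)` (all values must be positive). Finally
#' each sample column is median-centered. The result contains no missing
#' values; with `log_transform = FALSE` the operation is idempotent.
#'
#' @param mat an [omics_matrix()].
#' @param max_missing_frac maximum tolerated per-feature missing fraction.
#' @param log_transform apply `log2` after imputation?
#' @return the preprocessed [omics_matrix()].
#' @export
preprocess <- function(mat, max_missing_frac = 0.3, log_transform = FALSE) {
  check_fraction(max_missing_frac, "max_missing_frac")
  layer <- attr(mat, "layer") %||% "gene"
  miss_frac <- rowMeans(is.na(mat))
  keep <- miss_frac <= max_missing_frac
  if (!any(keep)) fail("all features removed by the missingness filter")
  m <- mat[keep, , drop = FALSE]
  na_idx <- which(is.na(m), arr.ind = TRUE)
  if (nrow(na_idx)) {
    fill_fun <- if (identical(layer, "metabolite")) {
      function(x) min(x, na.rm = TRUE) / 2
    } else {
      function(x) median(x, na.rm = TRUE)
    }
    fills <- apply(m, 1L, fill_fun)
    m[na_idx] <- fills[na_idx[, 1L]]
  }
  if (log_transform) {
    bad <- rownames(m)[apply(m <= 0, 1L, any)]
    if (length(bad))
      fail("non-positive values under log_transform for feature(s): %s",
           paste(bad, collapse = ", "))
    m <- log2(m)
  }
  m <- sweep(m, 2L, apply(m, 2L, median), "-")
  omics_matrix(m, layer)
}
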