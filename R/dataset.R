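#' Feature specification
#'
#' Describes a single attribute of a tabular dataset: a numeric feature with a
#' closed universe of discourse `[lo, hi]`, or a categorical feature with a
#' finite set of admissible values.
#'
#' @param name attribute name (unique within a dataset).
#' @param kind `"numeric"` or `"categorical"`.
#' @param universe numeric length-2 vector `c(lo, hi)` with `lo < hi`
#'   (numeric features only).
#' @param categories non-empty character vector of admissible values
#'   (categorical features only).
#' @return an object of class `fdx_feature`.
#' @export
feature_spec <- function(name, kind = c("numeric", "categorical"),
                         universe = NULL, categories = NULL) {
  kind <- match.arg(kind)
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (kind == "numeric") {
    if (is.null(universe) || length(universe) != 2L || !is.numeric(universe))
      stop_fdx("numeric feature '%s' needs a universe c(lo, hi)", name)
    if (!(universe[1] < universe[2]))
      stop_fdx("feature '%s': universe must satisfy lo < hi", name)
    universe <- as.numeric(universe)
    categories <- NULL
  } else {
    if (is.null(categories) || length(categories) == 0L)
      stop_fdx("categorical feature '%s' needs non-empty categories", name)
    categories <- as.character(categories)
    universe <- NULL
  }
  structure(list(name = name, kind = kind, universe = universe,
                 categories = categories),
            class = "fdx_feature")
}

#' Construct a dataset for rule learning
#'
#' Wraps a data frame together with per-feature domain metadata and the name
#' of the class attribute. Records must be complete: missing values are
#' rejected, not imputed. Numeric universes default to the observed
#' `[min, max]` per column and can be overridden.
#'
#' @param data a data.frame; every non-class column is a feature.
#' @param class name of the (categorical) class column.
#' @param universes optional named list of `c(lo, hi)` overrides for numeric
#'   features.
#' @return an object of class `fdx_dataset` with elements `data`, `class`,
#'   `features` (named list of [feature_spec()]) and `class_levels`.
#' @export
fdx_dataset <- function(data, class, universes = NULL) {
  stopifnot(is.data.frame(data))
  if (!class %in% names(data))
    stop_fdx("class attribute '%s' not found in data", class)
  bad_col <- lapply(data, function(v)
    is.na(v) | (if (is.character(v)) !nzchar(v) else FALSE))
  miss <- which(Reduce(`|`, bad_col, rep(FALSE, nrow(data))))
  if (length(miss) > 0L)
    stop_fdx("missing value(s) in row(s): %s", paste(miss, collapse = ", "))
  feats <- list()
  for (nm in setdiff(names(data), class)) {
    col <- data[[nm]]
    if (is.numeric(col)) {
      uni <- universes[[nm]] %||% range(col)
      if (uni[1] == uni[2]) uni <- uni + c(-0.5, 0.5)  # constant column
      feats[[nm]] <- feature_spec(nm, "numeric", universe = uni)
    } else {
      feats[[nm]] <- feature_spec(nm, "categorical",
                                  categories = sort(unique(as.character(col))))
      data[[nm]] <- as.character(col)
    }
  }
  cls <- as.character(data[[class]])
  if (length(unique(cls)) < 2L)
    warning(sprintf("class column '%s' is constant", class), call. = FALSE)
  data[[class]] <- cls
  structure(list(data = data, class = class, features = feats,
                 class_levels = sort(unique(cls))),
            class = "fdx_dataset")
}

#' @export
print.fdx_dataset <- function(x, ...) {
  tab <- table(x$data[[x$class]])
  cat(sprintf("Dataset: %d items, %d features, class '%s'\n",
              nrow(x$data), length(x$features), x$class))
  cat("  class distribution:",
      paste(sprintf("%s=%d", names(tab), as.integer(tab)), collapse = ", "),
      "\n")
  for (f in x$features) {
    if (f$kind == "numeric")
      cat(sprintf("  %s: numeric [%g, %g]\n", f$name, f$universe[1], f$universe[2]))
    else
      cat(sprintf("  %s: categorical {%s}\n", f$name,
                  paste(f$categories, collapse = ", ")))
  }
  invisible(x)
}

#' Read a dataset from CSV
#'
#' Reads a comma-separated file whose first row holds the attribute names.
#' A column is inferred numeric when every value parses as a number, and
#' categorical otherwise. Numeric universes are set to the observed
#' `[min, max]`. Any missing cell is an error naming the offending data row.
#'
#' @param path path to the CSV file.
#' @param class_attribute name of the class column (any position).
#' @param universes optional named list of numeric-universe overrides.
#' @return an [fdx_dataset()].
#' @export
read_dataset <- function(path, class_attribute, universes = NULL) {
  if (!file.exists(path)) stop_fdx("file not found: %s", path)
  raw <- utils::read.csv(path, colClasses = "character",
                         check.names = FALSE, strip.white = TRUE)
  if (!class_attribute %in% names(raw))
    stop_fdx("class attribute '%s' not in header (%s)",
             class_attribute, paste(names(raw), collapse = ", "))
  blank <- which(apply(is.na(raw) | raw == "", 1L, any))
  if (length(blank) > 0L)
    stop_fdx("missing value in row %s", paste(blank, collapse = ", "))
  for (nm in setdiff(names(raw), class_attribute)) {
    num <- suppressWarnings(as.numeric(raw[[nm]]))
    if (!anyNA(num)) raw[[nm]] <- num
  }
  fdx_dataset(raw, class_attribute, universes = universes)
}

#' Write a dataset to CSV
#'
#' Inverse of [read_dataset()]: plain comma-separated text, header row of
#' attribute names, no quoting beyond RFC 4180 needs.
#'
#' @param ds an [fdx_dataset()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(ds, path) {
  stopifnot(inherits(ds, "fdx_dataset"))
  utils::write.csv(ds$data, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Stratified k-fold partition
#'
#' Assigns every item to one of `k` folds so that, within each class, fold
#' sizes differ by at most one. Reproducible from `seed`.
#'
#' @param ds an [fdx_dataset()].
#' @param k number of folds (>= 2).
#' @param seed integer seed.
#' @return an object of class `fdx_folds`: list with `k`, `seed` and
#'   `assignments` (integer fold index per item).
#' @export
stratified_kfold <- function(ds, k, seed = 1L) {
  stopifnot(inherits(ds, "fdx_dataset"))
  n <- nrow(ds$data)
  if (k < 2L) stop_fdx("k must be >= 2")
  if (k > n) stop_fdx("k = %d exceeds the number of items (%d)", k, n)
  cls <- ds$data[[ds$class]]
  small <- names(which(table(cls) < k))
  if (length(small) > 0L)
    warning(sprintf("class(es) with fewer than k members: %s",
                    paste(small, collapse = ", ")), call. = FALSE)
  assignments <- integer(n)
  with_seed(seed, {
    for (cl in sort(unique(cls))) {
      idx <- which(cls == cl)
      idx <- idx[sample.int(length(idx))]
      assignments[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  structure(list(k = as.integer(k), seed = as.integer(seed),
                 assignments = assignments),
            class = "fdx_folds")
}

# Subset a dataset by item index, keeping feature metadata (universes fixed at
# the parent's so train/test folds share one universe of discourse).
dataset_subset <- function(ds, idx) {
  out <- ds
  out$data <- ds$data[idx, , drop = FALSE]
  rownames(out$data) <- NULL
  out
}
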