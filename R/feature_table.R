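#' Labeled feature table
#'
#' Container for a samples-by-features numeric matrix with a binary class
#' label per sample. This is the substrate every wrapper-selection and
#' evaluation function operates on.
#'
#' @param features numeric matrix (samples x features). Column names are
#'   assigned `f0..f{d-1}` when missing.
#' @param labels integer/numeric vector of 0/1 class labels, one per row of
#'   `features`. Class 1 is treated as the positive (typically minority)
#'   class throughout.
#' @return An object of class `feature_table`: a list with elements
#'   `features` (matrix) and `labels` (integer vector).
#' @examples
#' ft <- feature_table(matrix(rnorm(20), 10, 2), rep(c(0, 1), 5))
#' ft
#' @export
feature_table <- function(features, labels) {
  features <- as.matrix(features)
  storage.mode(features) <- "double"
  labels <- as.integer(labels)
  if (nrow(features) != length(labels)) {
    stop("feature_table: nrow(features) (", nrow(features),
         ") != length(labels) (", length(labels), ")")
  }
  if (!all(labels %in% c(0L, 1L))) {
    stop("feature_table: labels must be binary 0/1")
  }
  if (anyNA(features)) stop("feature_table: features contain NA")
  if (is.null(colnames(features))) {
    colnames(features) <- paste0("f", seq_len(ncol(features)) - 1L)
  }
  structure(list(features = features, labels = labels),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat("feature_table:", nrow(x$features), "samples x",
      ncol(x$features), "features; class counts:",
      paste(table(factor(x$labels, levels = 0:1)), collapse = "/"), "\n")
  invisible(x)
}

#' @export
dim.feature_table <- function(x) dim(x$features)

n_samples <- function(x) nrow(x$features)
n_features <- function(x) ncol(x$features)

#' Subset the rows of a feature table
#'
#' @param x a [feature_table()].
#' @param i row index vector.
#' @return a `feature_table` with the selected rows.
#' @keywords internal
ft_rows <- function(x, i) {
  feature_table(x$features[i, , drop = FALSE], x$labels[i])
}

#' Read / write the CSV feature-table dialect
#'
#' The on-disk dialect is a plain UTF-8 CSV with header `f0..f{d-1},label`,
#' `.` as decimal separator and labels in `{0, 1}`.
#'
#' @param path file path.
#' @return `read_feature_csv` returns a [feature_table()];
#'   `write_feature_csv` returns `path` invisibly.
#' @export
read_feature_csv <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  if (!"label" %in% names(df)) {
    stop("feature CSV must contain a 'label' column: ", path)
  }
  lab <- df[["label"]]
  df[["label"]] <- NULL
  feature_table(as.matrix(df), lab)
}

#' @param x a [feature_table()].
#' @rdname read_feature_csv
#' @export
write_feature_csv <- function(x, path) {
  stopifnot(inherits(x, "feature_table"))
  df <- as.data.frame(x$features)
  df$label <- x$labels
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Stratified train/test split
#'
#' Splits a feature table into a training and a held-out partition,
#' preserving the class proportions (per-class rounding).
#'
#' @param table a [feature_table()].
#' @param test_fraction fraction of each class assigned to the test
#'   partition (default 0.2).
#' @param seed integer seed controlling the split.
#' @return list with elements `train` and `test`, both `feature_table`s.
#' @export
train_test_split <- function(table, test_fraction = 0.2, seed = 1L) {
  stopifnot(inherits(table, "feature_table"),
            test_fraction > 0, test_fraction < 0.5)
  idx_test <- local_seed(seed, {
    unlist(lapply(c(0L, 1L), function(cl) {
      ic <- which(table$labels == cl)
      sample(ic, max(1L, round(test_fraction * length(ic))))
    }), use.names = FALSE)
  })
  list(train = ft_rows(table, setdiff(seq_len(n_samples(table)), idx_test)),
       test  = ft_rows(table, sort(idx_test)))
}

# Evaluate `expr` under set.seed(seed) without disturbing the caller's RNG
# stream (the optimizer's trajectory must not depend on cache hits).
local_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}
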