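#' Read a two-class expression table
#'
#' Reads a delimited expression table into a features x samples numeric
#' matrix. The first row must hold sample identifiers and the first column
#' feature identifiers (or the transpose, with
#' `orientation = "samples_by_features"`). Identifiers must be unique and
#' every data cell numeric.
#'
#' @param path Path to the table.
#' @param dialect `"tsv"` (default) or `"csv"`.
#' @param orientation `"features_by_samples"` (microarray convention,
#'   default) or `"samples_by_features"`; the returned matrix is always
#'   features x samples.
#' @param na_action What to do with missing cells: `"error"` (default)
#'   aborts citing the cell coordinates; `"impute_row_mean"` replaces each
#'   missing value with the mean of the remaining values in its feature row
#'   and emits a message.
#' @return Numeric matrix, features in rows, samples in columns, with
#'   `rownames` the feature identifiers and `colnames` the sample
#'   identifiers.
#' @export
read_expression_table <- function(path,
                                  dialect = c("tsv", "csv"),
                                  orientation = c("features_by_samples",
                                                  "samples_by_features"),
                                  na_action = c("error", "impute_row_mean")) {
  dialect <- match.arg(dialect)
  orientation <- match.arg(orientation)
  na_action <- match.arg(na_action)
  if (!file.exists(path)) stop("file does not exist: ", path)
  sep <- if (dialect == "tsv") "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep, row.names = NULL,
                          check.names = FALSE, colClasses = "character",
                          stringsAsFactors = FALSE, quote = "\"",
                          comment.char = "")
  if (nrow(df) == 0L || ncol(df) < 2L) stop("empty expression table: ", path)
  row_ids <- df[[1L]]
  col_ids <- colnames(df)[-1L]
  dup <- unique(row_ids[duplicated(row_ids)])
  if (length(dup)) stop("duplicate row identifier(s): ",
                        paste(dup, collapse = ", "))
  dup <- unique(col_ids[duplicated(col_ids)])
  if (length(dup)) stop("duplicate column identifier(s): ",
                        paste(dup, collapse = ", "))

  cells <- as.matrix(df[, -1L, drop = FALSE])
  vals <- suppressWarnings(matrix(as.numeric(cells), nrow = nrow(cells)))
  dimnames(vals) <- list(row_ids, col_ids)

  bad <- which(is.na(vals) & !is.na(cells) & toupper(trimws(cells)) != "NA",
               arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("non-numeric cell '%s' at row '%s', column '%s'",
                 cells[bad[1L, 1L], bad[1L, 2L]],
                 row_ids[bad[1L, 1L]], col_ids[bad[1L, 2L]]))
  }
  miss <- which(!is.finite(vals), arr.ind = TRUE)
  if (nrow(miss)) {
    if (na_action == "error") {
      stop(sprintf("missing/non-finite value at row '%s', column '%s'",
                   row_ids[miss[1L, 1L]], col_ids[miss[1L, 2L]]))
    }
    for (r in unique(miss[, 1L])) {
      ok <- is.finite(vals[r, ])
      if (!any(ok)) stop("row '", row_ids[r], "' has no finite values to impute from")
      vals[r, !ok] <- mean(vals[r, ok])
    }
    message("imputed ", nrow(miss), " missing value(s) with row means")
  }
  if (orientation == "samples_by_features") vals <- t(vals)
  vals
}

#' Write an expression matrix
#'
#' Writes a features x samples matrix in the format read by
#' [read_expression_table()], printing values with 17 significant digits so
#' a write/read round trip reproduces them exactly.
#'
#' @param x Numeric matrix with feature rownames and sample colnames.
#' @param path Output path.
#' @param dialect `"tsv"` or `"csv"`.
#' @export
write_expression_table <- function(x, path, dialect = c("tsv", "csv")) {
  dialect <- match.arg(dialect)
  stopifnot(is.matrix(x), !is.null(rownames(x)), !is.null(colnames(x)))
  sep <- if (dialect == "tsv") "\t" else ","
  header <- paste(c("feature_id", colnames(x)), collapse = sep)
  body <- vapply(seq_len(nrow(x)), function(i) {
    paste(c(rownames(x)[i], sprintf("%.17g", x[i, ])), collapse = sep)
  }, character(1L))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read two-class sample labels
#'
#' Reads a two-column table (sample identifier, class string) and encodes
#' the two classes as +1/-1. If `positive_label` is not given, the
#' lexicographically smaller class string (C collation) maps to +1.
#'
#' @param path Path to a headerless or headered two-column TSV/CSV.
#' @param sample_ids Optional character vector giving the order of samples
#'   (typically `colnames` of the expression matrix); labels are aligned to
#'   it and any mismatch between the two sample sets is an error.
#' @param positive_label Optional class string to map to +1.
#' @param dialect `"tsv"` or `"csv"`.
#' @return An object of class `class_labels`: a list with `labels` (named
#'   integer vector of +1/-1) and `mapping` (named vector, original class
#'   string -> code).
#' @export
read_labels <- function(path, sample_ids = NULL, positive_label = NULL,
                        dialect = c("tsv", "csv")) {
  dialect <- match.arg(dialect)
  sep <- if (dialect == "tsv") "\t" else ","
  df <- utils::read.table(path, header = FALSE, sep = sep,
                          colClasses = "character", stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("labels file must have two columns (sample_id, class)")
  # tolerate a header line
  if (identical(tolower(df[1L, 1L]), "sample_id")) df <- df[-1L, , drop = FALSE]
  class_labels(stats::setNames(df[[2L]], df[[1L]]),
               sample_ids = sample_ids, positive_label = positive_label)
}

#' Construct class labels from a named vector of class strings
#'
#' @param labels Named character (or factor/numeric) vector, one entry per
#'   sample; exactly two distinct values.
#' @inheritParams read_labels
#' @return A `class_labels` object.
#' @export
class_labels <- function(labels, sample_ids = NULL, positive_label = NULL) {
  labels <- stats::setNames(as.character(labels), names(labels))
  classes <- sort(unique(labels), method = "radix")
  if (length(classes) != 2L) {
    stop("expected exactly 2 classes, found ", length(classes), ": ",
         paste(classes, collapse = ", "))
  }
  if (is.null(positive_label)) {
    positive_label <- classes[1L]  # lexicographically smaller string
  } else if (!positive_label %in% classes) {
    stop("positive_label '", positive_label, "' not among the classes")
  }
  if (!is.null(sample_ids)) {
    if (is.null(names(labels))) stop("labels must be named to align to sample_ids")
    missing_lab <- setdiff(sample_ids, names(labels))
    extra_lab <- setdiff(names(labels), sample_ids)
    if (length(missing_lab) || length(extra_lab)) {
      stop("sample sets differ; missing from labels: [",
           paste(missing_lab, collapse = ", "), "]; absent from matrix: [",
           paste(extra_lab, collapse = ", "), "]")
    }
    labels <- labels[sample_ids]
  }
  code <- ifelse(labels == positive_label, 1L, -1L)
  mapping <- stats::setNames(c(1L, -1L),
                             c(positive_label, setdiff(classes, positive_label)))
  structure(list(labels = stats::setNames(as.integer(code), names(labels)),
                 mapping = mapping),
            class = "class_labels")
}

#' @export
print.class_labels <- function(x, ...) {
  cat("class_labels:", sum(x$labels == 1L), "positive /",
      sum(x$labels == -1L), "negative samples\n")
  cat("mapping:", paste(names(x$mapping), x$mapping, sep = " -> ",
                        collapse = ", "), "\n")
  invisible(x)
}

# Coerce labels (class_labels, factor, or +1/-1 vector) to an integer
# +1/-1 vector; errors unless both classes are present.
as_pm1 <- function(y, n = NULL) {
  if (inherits(y, "class_labels")) y <- y$labels
  if (is.factor(y)) y <- as.character(y)
  yv <- suppressWarnings(as.integer(y))
  if (anyNA(yv) || !all(yv %in% c(-1L, 1L))) {
    stop("labels must be a class_labels object or a vector of +1/-1")
  }
  if (!is.null(n) && length(yv) != n) {
    stop("label length (", length(yv), ") does not match sample count (", n, ")")
  }
  if (length(unique(yv)) < 2L) stop("both classes must be present")
  yv
}

#' Quantile normalization of an expression matrix
#'
#' Forces every sample column to the common reference distribution given by
#' the row-wise means of the per-column sorted values, preserving each
#' column's internal ordering. Tied values within a column receive the mean
#' of the reference values over the tied rank range. Delegates to
#' [limma::normalizeQuantiles()].
#'
#' @param x Features x samples numeric matrix with at least two columns and
#'   finite entries.
#' @return Matrix of the same shape and dimnames.
#' @export
quantile_normalize <- function(x) {
  stopifnot(is.matrix(x))
  if (ncol(x) < 2L) stop("quantile normalization needs >= 2 samples")
  if (any(!is.finite(x))) stop("matrix contains non-finite values")
  out <- limma::normalizeQuantiles(x, ties = TRUE)
  dimnames(out) <- dimnames(x)
  out
}

#' Write / read a ranked feature list as TSV
#'
#' Columns: `rank` (1 = best), `feature_id`, `criterion_value` (the
#' ranking-criterion value the feature had at the iteration it was
#' eliminated; `NA` for rankings without criteria, e.g. aggregated ones).
#'
#' @param rl A `ranked_list` (or `ensemble_ranking`) object.
#' @param path Output path.
#' @export
write_ranked_list <- function(rl, path) {
  if (inherits(rl, "ensemble_ranking")) {
    ids <- rl$feature_ids[rl$final_order]
    crit <- rl$aggregated[rl$final_order]
  } else {
    ids <- rl$feature_ids
    crit <- rl$criterion_at_removal
  }
  df <- data.frame(rank = seq_along(ids), feature_id = ids,
                   criterion_value = sprintf("%.17g", crit))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ranked_list
#' @return `read_ranked_list()` returns a data.frame with columns `rank`,
#'   `feature_id`, `criterion_value`.
#' @export
read_ranked_list <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE,
                          colClasses = c("integer", "character", "numeric"))
  if (!identical(df$rank, seq_len(nrow(df)))) stop("ranks are not 1..n in order")
  df
}

#' Samples-to-dimensions ratio
#'
#' The number of samples divided by the number of features (probes), the
#' standard summary of how underdetermined an expression data set is.
#'
#' @param samples,probes Positive counts (vectorized).
#' @return `samples / probes`.
#' @export
sdr <- function(samples, probes) {
  stopifnot(all(samples > 0), all(probes > 0))
  samples / probes
}

#' Characteristics of the benchmark microarray data sets
#'
#' Returns the bundled table of GEO data-set characteristics (accession,
#' sample count, probe count, cancer type, and the published
#' samples-to-dimensions ratio) used in the worked examples.
#'
#' @return data.frame with columns `dataset`, `samples`, `probes`,
#'   `classes`, `sdr_published`, `type`.
#' @export
dataset_characteristics <- function() {
  path <- system.file("extdata", "dataset_characteristics.tsv",
                      package = "sigrfe", mustWork = TRUE)
  utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}
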