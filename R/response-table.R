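#' Build a validated response table
#'
#' A response table holds trial-averaged scalar responses of several
#' individuals (rows) to several odors (columns). It is the universal input
#' to the stereotypy metrics. Accepted inputs are a numeric matrix with row
#' and column names, or a data frame whose first column (or a column named
#' `individual`) carries the individual labels and whose remaining columns
#' are numeric odor responses.
#'
#' @param x A matrix or data frame as described above.
#' @param require_pairs If `TRUE` (the default for metric computations),
#'   require at least 2 individuals and 2 odors.
#'
#' @return A tibble with an `individual` character column followed by one
#'   numeric column per odor.
#' @examples
#' response_table(matrix(1:6, 2, 3, dimnames = list(c("A", "B"), c("o1", "o2", "o3"))))
#' @export
response_table <- function(x, require_pairs = TRUE) {
  m <- as_response_matrix(x, require_pairs = require_pairs)
  tibble::as_tibble(as.data.frame(m), rownames = "individual")
}

# Internal canonical form: numeric matrix, individuals x odors, dimnames set.
as_response_matrix <- function(x, require_pairs = TRUE) {
  if (is.data.frame(x)) {
    df <- as.data.frame(x)
    id_col <- if ("individual" %in% names(df)) "individual" else names(df)[1]
    if (is.numeric(df[[id_col]]) && id_col == names(df)[1] && !("individual" %in% names(df))) {
      # purely numeric frame: rows are individuals, use rownames
      m <- as.matrix(df)
      rownames(m) <- rownames(df) %||% paste0("ind", seq_len(nrow(m)))
    } else {
      labels <- as.character(df[[id_col]])
      df[[id_col]] <- NULL
      if (!all(vapply(df, is.numeric, logical(1)))) {
        bad <- names(df)[!vapply(df, is.numeric, logical(1))]
        abort(paste0("Non-numeric response column(s): ", paste(bad, collapse = ", ")))
      }
      m <- as.matrix(df)
      rownames(m) <- labels
    }
  } else if (is.matrix(x)) {
    m <- x
    storage.mode(m) <- "double"
    if (is.null(rownames(m))) rownames(m) <- paste0("ind", seq_len(nrow(m)))
    if (is.null(colnames(m))) colnames(m) <- paste0("odor", seq_len(ncol(m)))
  } else {
    abort("A response table must be a matrix or a data frame.")
  }
  if (anyNA(m) || !all(is.finite(m))) {
    bad <- which(!is.finite(m), arr.ind = TRUE)[1, , drop = TRUE]
    abort(sprintf(
      "Non-finite response at individual '%s', odor '%s'.",
      rownames(m)[bad[1]], colnames(m)[bad[2]]
    ))
  }
  if (anyDuplicated(rownames(m))) abort("Duplicated individual labels.")
  if (anyDuplicated(colnames(m))) abort("Duplicated odor labels.")
  if (require_pairs) {
    if (nrow(m) < 2) abort("At least 2 individuals are required (rows).")
    if (ncol(m) < 2) abort("At least 2 odors are required (columns).")
  }
  m
}

#' Read a response table from a delimited text file
#'
#' The file must have a header row of odor labels and a first column of
#' individual labels; all cells must be numeric and non-missing.
#'
#' @param path Path to a CSV (or other delimited) file.
#' @param delim Field delimiter, `","` by default.
#' @return A response-table tibble (see [response_table()]).
#' @export
read_response_table <- function(path, delim = ",") {
  df <- utils::read.table(path,
    header = TRUE, sep = delim, check.names = FALSE,
    stringsAsFactors = FALSE
  )
  if (nrow(df) < 2 || ncol(df) < 3) {
    abort("Response table files need >= 2 individuals and >= 2 odors.")
  }
  labels <- as.character(df[[1]])
  vals <- df[-1]
  for (j in seq_along(vals)) {
    v <- vals[[j]]
    if (is.character(v)) v <- suppressWarnings(as.numeric(v))
    if (anyNA(v)) {
      i <- which(is.na(v))[1]
      abort(sprintf(
        "Missing or non-numeric value at row '%s', column '%s'.",
        labels[i], names(vals)[j]
      ))
    }
    vals[[j]] <- v
  }
  m <- as.matrix(vals)
  rownames(m) <- labels
  response_table(m)
}

#' Write a response table to CSV
#'
#' @param table A response table (tibble or matrix).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_response_table <- function(table, path) {
  m <- as_response_matrix(table, require_pairs = FALSE)
  df <- data.frame(individual = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path,
    sep = ",", row.names = FALSE, quote = FALSE
  )
  invisible(path)
}
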