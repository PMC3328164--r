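`%||%` <- function(a, b) if (is.null(a)) b else a

# Scale columns of Q by the column-weight metric: returns W %*% Q for a
# diagonal (vector) or full symmetric weight matrix.
weight_times <- function(w, Q) {
  if (is.matrix(w)) w %*% Q else Q * w
}

# Squared generalized norm of each row of X under metric w.
row_wnorm2 <- function(X, w) {
  if (is.matrix(w)) rowSums((X %*% w) * X) else rowSums(sweep(X^2, 2, w, "*"))
}

stop_ <- function(...) stop(sprintf(...), call. = FALSE)

check_numeric_matrix <- function(x, what = "data") {
  x <- as.matrix(x)
  if (!is.numeric(x)) stop_("%s must be a numeric matrix", what)
  if (any(!is.finite(x))) stop_("%s contains non-finite values", what)
  x
}

# Full-precision numeric CSV writer/reader so round trips preserve doubles.
write_matrix_csv <- function(x, path, row_label = NULL, row_ids = NULL) {
  x <- as.matrix(x)
  cn <- colnames(x) %||% paste0("V", seq_len(ncol(x)))
  body <- apply(x, 1, function(r) paste(sprintf("%.17g", r), collapse = ","))
  if (length(body) == 0) body <- character(0)
  if (!is.null(row_ids)) {
    header <- paste(c(row_label %||% "id", cn), collapse = ",")
    body <- paste(row_ids, body, sep = ",")
  } else {
    header <- paste(cn, collapse = ",")
  }
  writeLines(c(header, body), path)
}

read_matrix_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  ids <- NULL
  if (ncol(df) > 0 && (names(df)[1] %in% c("id", "row_id") || !is.numeric(df[[1]]))) {
    ids <- as.character(df[[1]])
    df[[1]] <- NULL
  }
  x <- as.matrix(df)
  if (!is.numeric(x)) stop_("non-numeric cells in %s", path)
  if (!is.null(ids)) rownames(x) <- ids
  x
}
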