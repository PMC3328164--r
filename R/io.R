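#' Read a table and its designs from delimited text files
#'
#' The matrix file is a CSV with a header of column IDs and optionally a
#' leading `row_id` column. The row design CSV has columns `row_id`,
#' `category` and optionally `block`, one record per matrix row in order;
#' the column design CSV has columns `col_id` and `subtable`, one record
#' per matrix column. IDs are checked against the matrix: a mismatch is an
#' error, not a warning -- silent reordering of rows or voxels is the
#' classic multivariate-pattern-analysis bug this guards against.
#'
#' @param matrix_file path to the data matrix CSV.
#' @param row_design_file path to the row design CSV.
#' @param col_design_file path to the column design CSV.
#' @param masses_file optional CSV with a `mass` column (one per row).
#' @param weights_file optional CSV with a `weight` column (one per
#'   column).
#' @return a [discriminant_table()].
#' @export
read_discriminant_table <- function(matrix_file, row_design_file,
                                    col_design_file, masses_file = NULL,
                                    weights_file = NULL) {
  X <- read_matrix_csv(matrix_file)
  rows <- utils::read.csv(row_design_file, stringsAsFactors = FALSE)
  if (!all(c("row_id", "category") %in% names(rows)))
    stop_("row design must have columns 'row_id' and 'category'")
  if (nrow(rows) != nrow(X))
    stop_("row design has %d records but matrix has %d rows",
          nrow(rows), nrow(X))
  if (!is.null(rownames(X)) &&
      !identical(as.character(rownames(X)), as.character(rows$row_id)))
    stop_("row IDs in the matrix and the row design do not match")

  cols <- utils::read.csv(col_design_file, stringsAsFactors = FALSE)
  if (!all(c("col_id", "subtable") %in% names(cols)))
    stop_("column design must have columns 'col_id' and 'subtable'")
  if (nrow(cols) != ncol(X))
    stop_("column design has %d records but matrix has %d columns",
          nrow(cols), ncol(X))
  if (!is.null(colnames(X)) &&
      !identical(as.character(colnames(X)), as.character(cols$col_id)))
    stop_("column IDs in the matrix and the column design do not match")

  m <- NULL
  if (!is.null(masses_file)) {
    mdf <- utils::read.csv(masses_file)
    if (!"mass" %in% names(mdf)) stop_("masses file must have a 'mass' column")
    m <- as.numeric(mdf$mass)
  }
  w <- NULL
  if (!is.null(weights_file)) {
    wdf <- utils::read.csv(weights_file)
    if (!"weight" %in% names(wdf))
      stop_("weights file must have a 'weight' column")
    w <- as.numeric(wdf$weight)
  }
  discriminant_table(X, rows$category,
                     row_blocks = if ("block" %in% names(rows)) rows$block,
                     col_subtables = cols$subtable,
                     row_masses = m, col_weights = w)
}

#' Write a table and its designs as the three-file CSV interchange
#'
#' Emits `matrix.csv`, `rows.csv` and `cols.csv` in the format
#' [read_discriminant_table()] consumes, at full double precision.
#'
#' @param table a [discriminant_table()].
#' @param dir output directory (created if needed).
#' @return the paths, invisibly.
#' @export
write_discriminant_table <- function(table, dir) {
  stopifnot(inherits(table, "discriminant_table"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  N <- nrow(table$data)
  row_ids <- rownames(table$data) %||% sprintf("r%d", seq_len(N))
  col_ids <- colnames(table$data) %||% sprintf("v%d", seq_len(ncol(table$data)))
  mat <- table$data
  colnames(mat) <- col_ids
  paths <- file.path(dir, c("matrix.csv", "rows.csv", "cols.csv"))
  write_matrix_csv(mat, paths[1], row_label = "row_id", row_ids = row_ids)
  rows <- data.frame(row_id = row_ids,
                     category = as.character(table$row_categories))
  if (!is.null(table$row_blocks))
    rows$block <- as.character(table$row_blocks)
  utils::write.csv(rows, paths[2], row.names = FALSE)
  utils::write.csv(data.frame(col_id = col_ids,
                              subtable = as.character(table$col_subtables)),
                   paths[3], row.names = FALSE)
  invisible(paths)
}

#' Write analysis results as delimited text plus a JSON manifest
#'
#' Writes the category factor scores, variable loadings, inertia table and
#' -- when available -- fixed and random confusion matrices and ellipse
#' parameters, each as CSV, plus `manifest.json` recording the
#' configuration, seed and which optional outputs are present. Identical
#' configuration and seed reproduce every file bit-for-bit.
#'
#' @param model a fitted `bada` model.
#' @param dir output directory.
#' @param fixed_report,random_report optional `bada_classification`
#'   objects.
#' @param ellipses optional list of `bada_ellipse` objects (named by
#'   category).
#' @param config optional list recorded verbatim in the manifest.
#' @param seed optional seed recorded in the manifest.
#' @return the manifest, invisibly.
#' @export
write_results <- function(model, dir, fixed_report = NULL,
                          random_report = NULL, ellipses = NULL,
                          config = list(), seed = NULL) {
  stopifnot(inherits(model, "bada"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  wf <- function(x, name, ids = NULL, label = "id") {
    path <- file.path(dir, name)
    write_matrix_csv(x, path, row_label = label, row_ids = ids)
    files <<- c(files, name)
  }
  wf(model$F, "factor_scores.csv", ids = rownames(model$F), label = "category")
  wf(model$G, "loadings.csv", ids = rownames(model$G) %||%
       sprintf("v%d", seq_len(nrow(model$G))), label = "col_id")
  ine <- inertia_decomposition(model)
  utils::write.csv(data.frame(total = ine$total, within = ine$within,
                              between = ine$between,
                              r_squared = ine$r_squared),
                   file.path(dir, "inertia.csv"), row.names = FALSE)
  files <- c(files, "inertia.csv")
  if (!is.null(fixed_report)) {
    utils::write.csv(as.data.frame.matrix(fixed_report$confusion),
                     file.path(dir, "confusion_fixed.csv"))
    files <- c(files, "confusion_fixed.csv")
  }
  if (!is.null(random_report)) {
    utils::write.csv(as.data.frame.matrix(random_report$confusion),
                     file.path(dir, "confusion_random.csv"))
    files <- c(files, "confusion_random.csv")
  }
  if (!is.null(ellipses)) {
    utils::write.csv(ellipse_df(ellipses), file.path(dir, "ellipses.csv"),
                     row.names = FALSE)
    files <- c(files, "ellipses.csv")
  }
  manifest <- list(
    package = "musubada",
    variant = model$variant,
    files = files,
    config = config,
    seed = seed,
    absent = setdiff(c("confusion_fixed.csv", "confusion_random.csv",
                       "ellipses.csv"), files),
    eigenvalues = model$decomp$eigenvalues
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Persist a fitted model as a directory of CSVs plus JSON metadata
#'
#' The model directory is plain text -- inspectable and diffable -- and
#' [load_model()] restores an object that supports [classify()],
#' [project_rows()], [partial_scores()] and [partial_inertia()].
#'
#' @param model a fitted `bada` model.
#' @param dir directory to create.
#' @return `dir`, invisibly.
#' @export
save_model <- function(model, dir) {
  stopifnot(inherits(model, "bada"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_matrix_csv(model$R, file.path(dir, "barycenters.csv"))
  write_matrix_csv(model$decomp$Q, file.path(dir, "Q.csv"))
  write_matrix_csv(model$F, file.path(dir, "F.csv"))
  write_matrix_csv(model$G, file.path(dir, "G.csv"))
  write_matrix_csv(model$H, file.path(dir, "H.csv"))
  if (is.matrix(model$w))
    write_matrix_csv(model$w, file.path(dir, "W.csv"))
  meta <- list(
    variant = model$variant,
    categories = model$categories,
    row_categories = as.character(model$row_categories),
    row_blocks = if (!is.null(model$row_blocks)) as.character(model$row_blocks),
    col_subtables = as.character(model$col_subtables),
    b = model$b,
    w = if (!is.matrix(model$w)) model$w,
    m = model$m,
    delta = model$decomp$delta,
    L = model$decomp$L,
    n_components = model$n_components,
    preprocess = lapply(model$preprocess, function(st) {
      st$rv <- NULL  # inspection-only matrix, not needed for replay
      st
    })
  )
  jsonlite::write_json(meta, file.path(dir, "model.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' @rdname save_model
#' @param dir the directory written by `save_model`.
#' @return `load_model`: a `bada` object.
#' @export
load_model <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "model.json"),
                              simplifyVector = TRUE,
                              simplifyDataFrame = FALSE)
  Q <- read_matrix_csv(file.path(dir, "Q.csv"))
  w <- if (file.exists(file.path(dir, "W.csv")))
    read_matrix_csv(file.path(dir, "W.csv")) else as.numeric(meta$w)
  delta <- as.numeric(meta$delta)
  pp <- lapply(meta$preprocess, function(st) {
    st <- as.list(st)
    for (nm in setdiff(names(st), "step")) st[[nm]] <- as.numeric(st[[nm]])
    st
  })
  structure(list(
    variant = meta$variant,
    preprocess = pp,
    Xp = NULL,
    R = read_matrix_csv(file.path(dir, "barycenters.csv")),
    b = as.numeric(meta$b),
    w = w,
    WQ = weight_times(w, Q),
    decomp = structure(list(P = NULL, Q = Q, delta = delta,
                            eigenvalues = delta^2, L = meta$L),
                       class = "gsvd"),
    F = read_matrix_csv(file.path(dir, "F.csv")),
    G = read_matrix_csv(file.path(dir, "G.csv")),
    H = read_matrix_csv(file.path(dir, "H.csv")),
    m = as.numeric(meta$m),
    categories = meta$categories,
    row_categories = factor(meta$row_categories, levels = meta$categories),
    row_blocks = if (length(meta$row_blocks)) factor(unlist(meta$row_blocks)),
    col_subtables = factor(meta$col_subtables,
                           levels = unique(meta$col_subtables)),
    n_components = if (length(meta$n_components))
      as.integer(meta$n_components),
    within_cov_condition = NULL
  ), class = "bada")
}
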