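#' Assemble an observations-by-variables table with its designs
#'
#' The central data container: a numeric matrix of `N` observations (rows,
#' e.g. scans) by `J` variables (columns, e.g. voxels), together with a row
#' design (one category per observation, optionally one block label), a
#' column design (one subtable per variable, e.g. the participant or ROI a
#' voxel belongs to), row masses and column weights.
#'
#' Masses weight observations when barycenters are computed; weights define
#' the generalized Euclidean metric between row profiles. Defaults are the
#' uniform mass `1/N` and weight `1/J`. Category masses default to the row
#' masses aggregated within each category, which is what the barycenter
#' rescaling implies; they may be overridden. Subtable weights are stored and
#' exposed for completeness but enter no computation unless the user folds
#' them into the column weights.
#'
#' @param data numeric matrix, `N x J`.
#' @param row_categories category label per row; coerced to factor. At least
#'   two categories, each non-empty.
#' @param row_blocks optional block label per row (temporally contiguous
#'   scans that should be treated as one exchangeable/resampling unit).
#' @param col_subtables optional subtable label per column; default a single
#'   subtable.
#' @param row_masses nonnegative, default `1/N` each.
#' @param col_weights strictly positive, default `1/J` each.
#' @param category_masses optional override, one nonnegative value per
#'   category (in level order).
#' @param subtable_weights optional, one positive value per subtable.
#' @return an object of class `discriminant_table`.
#' @examples
#' x <- matrix(rnorm(12), 4, 3)
#' tab <- discriminant_table(x, c("a", "a", "b", "b"))
#' tab$row_masses
#' @export
discriminant_table <- function(data, row_categories, row_blocks = NULL,
                               col_subtables = NULL, row_masses = NULL,
                               col_weights = NULL, category_masses = NULL,
                               subtable_weights = NULL) {
  data <- check_numeric_matrix(data)
  N <- nrow(data)
  J <- ncol(data)
  if (length(row_categories) != N)
    stop_("row design has %d records but matrix has %d rows",
          length(row_categories), N)
  row_categories <- droplevels(as.factor(row_categories))
  if (anyNA(row_categories)) stop_("missing category label")
  I <- nlevels(row_categories)
  if (I < 2) stop_("need at least two categories, got %d", I)
  if (N < I) stop_("fewer rows (%d) than categories (%d)", N, I)

  if (!is.null(row_blocks)) {
    if (length(row_blocks) != N)
      stop_("block design has %d records but matrix has %d rows",
            length(row_blocks), N)
    row_blocks <- droplevels(as.factor(row_blocks))
  }

  if (is.null(col_subtables)) col_subtables <- rep("T1", J)
  if (length(col_subtables) != J)
    stop_("column design has %d records but matrix has %d columns",
          length(col_subtables), J)
  col_subtables <- factor(col_subtables, levels = unique(as.character(col_subtables)))
  K <- nlevels(col_subtables)

  row_masses <- row_masses %||% rep(1 / N, N)
  if (length(row_masses) != N) stop_("row_masses must have length %d", N)
  if (any(row_masses < 0) || any(!is.finite(row_masses)))
    stop_("row masses must be finite and nonnegative")

  col_weights <- col_weights %||% rep(1 / J, J)
  if (length(col_weights) != J) stop_("col_weights must have length %d", J)
  if (any(col_weights <= 0) || any(!is.finite(col_weights)))
    stop_("column weights must be finite and strictly positive")

  cat_mass_default <- as.numeric(tapply(row_masses, row_categories, sum))
  if (any(cat_mass_default <= 0))
    stop_("category '%s' has zero total mass",
          levels(row_categories)[which(cat_mass_default <= 0)[1]])
  category_masses <- category_masses %||% cat_mass_default
  if (length(category_masses) != I)
    stop_("category_masses must have length %d", I)
  if (any(category_masses < 0)) stop_("category masses must be nonnegative")

  subtable_weights <- subtable_weights %||% rep(1 / K, K)
  if (length(subtable_weights) != K)
    stop_("subtable_weights must have length %d", K)
  if (any(subtable_weights <= 0)) stop_("subtable weights must be positive")

  structure(list(
    data = data,
    row_categories = row_categories,
    row_blocks = row_blocks,
    col_subtables = col_subtables,
    row_masses = as.numeric(row_masses),
    col_weights = as.numeric(col_weights),
    category_masses = as.numeric(category_masses),
    subtable_weights = as.numeric(subtable_weights)
  ), class = "discriminant_table")
}

#' @export
print.discriminant_table <- function(x, ...) {
  cat(sprintf("discriminant_table: %d observations x %d variables\n",
              nrow(x$data), ncol(x$data)))
  cat(sprintf("  categories (%d): %s\n", nlevels(x$row_categories),
              paste(levels(x$row_categories), collapse = ", ")))
  if (!is.null(x$row_blocks))
    cat(sprintf("  blocks: %d\n", nlevels(x$row_blocks)))
  jk <- table(x$col_subtables)
  cat(sprintf("  subtables (%d): %s\n", length(jk),
              paste(sprintf("%s[%d]", names(jk), jk), collapse = ", ")))
  invisible(x)
}

#' Subset a table by rows, keeping the category level set
#'
#' Used by cross-validation: the fold table keeps the full category level
#' set so confusion matrices from different folds stay aligned. Category
#' masses are re-aggregated from the retained row masses.
#'
#' @param table a `discriminant_table`.
#' @param rows integer or logical row index.
#' @return a `discriminant_table` over the selected rows.
#' @export
table_subset <- function(table, rows) {
  stopifnot(inherits(table, "discriminant_table"))
  cats <- table$row_categories[rows]
  if (any(tabulate(cats, nbins = nlevels(cats)) == 0))
    stop_("subset empties category '%s'",
          levels(cats)[which(tabulate(cats, nbins = nlevels(cats)) == 0)[1]])
  m <- table$row_masses[rows]
  structure(list(
    data = table$data[rows, , drop = FALSE],
    row_categories = cats,
    row_blocks = if (!is.null(table$row_blocks)) droplevels(table$row_blocks[rows]),
    col_subtables = table$col_subtables,
    row_masses = m,
    col_weights = table$col_weights,
    category_masses = as.numeric(tapply(m, cats, sum)),
    subtable_weights = table$subtable_weights
  ), class = "discriminant_table")
}
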