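#' Two-level grouped dataset
#'
#' Container for a clustered or longitudinal dataset: a response vector, a
#' fixed-effects design matrix and a group (cluster) label per row.  Groups
#' are indexed in order of first appearance.
#'
#' @param y Numeric response vector, length `n`.
#' @param X Fixed-effects design matrix (`n x p`), full column rank.  A
#'   plain vector is treated as a single column.  Column names are kept
#'   (unnamed columns are labelled `x1`, `x2`, ...).
#' @param group Vector of group labels, length `n` (any atomic type).
#' @return An object of class `"grouped_data"`: list with `y`, `X`,
#'   `group` (integer codes 1..d in first-appearance order),
#'   `group_labels`, `sizes` (n_j per group), `n`, `d`, `p`.
#' @examples
#' d <- grouped_data(rnorm(6), cbind(1, 1:6), c("a", "a", "b", "b", "b", "a"))
#' d$sizes
#' @export
grouped_data <- function(y, X, group) {
  y <- as.numeric(y)
  X <- as.matrix(X)
  n <- length(y)
  if (nrow(X) != n) stop("nrow(X) must equal length(y)", call. = FALSE)
  if (length(group) != n)
    stop("'group' must have one label per observation", call. = FALSE)
  if (anyNA(y) || anyNA(X) || anyNA(group))
    stop("missing values are not allowed in y, X or group", call. = FALSE)
  if (qr(X)$rank < ncol(X))
    stop("design matrix is rank deficient", call. = FALSE)
  labels <- unique(group)
  g <- match(group, labels)
  if (is.null(colnames(X)))
    colnames(X) <- paste0("x", seq_len(ncol(X)))
  structure(list(
    y = y, X = X, group = g,
    group_labels = as.character(labels),
    sizes = tabulate(g, nbins = length(labels)),
    n = n, d = length(labels), p = ncol(X)
  ), class = "grouped_data")
}

#' @export
print.grouped_data <- function(x, ...) {
  cat(sprintf("Grouped dataset: n = %d observations, d = %d groups, p = %d covariates\n",
              x$n, x$d, x$p))
  cat(sprintf("Group sizes: min %d, median %g, max %d\n",
              min(x$sizes), stats::median(x$sizes), max(x$sizes)))
  invisible(x)
}
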