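#' Read a long-format delimited table into a grouped dataset
#'
#' Reads a delimited text file with a header row (one row per measurement
#' occasion), drops rows with missing values in any referenced column
#' (with a message giving the count), expands categorical covariates to
#' indicator columns using the first-observed level as the baseline, and
#' prepends an intercept column.
#'
#' @param path Path to a delimited text file.
#' @param response Name of the response column.
#' @param group Name of the group / cluster identifier column.
#' @param fixed Character vector of fixed-effect covariate column names
#'   (may be empty: intercept-only model).
#' @param sep Field separator (default comma).
#' @return A [grouped_data()] object.  The design matrix contains an
#'   `(Intercept)` column followed by the (possibly expanded) covariates.
#' @export
read_long_table <- function(path, response, group, fixed = character(),
                            sep = ",") {
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE)
  cols <- c(response, group, fixed)
  missing_cols <- setdiff(cols, names(tab))
  if (length(missing_cols))
    stop("columns not found in ", path, ": ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  keep <- stats::complete.cases(tab[, cols, drop = FALSE])
  if (!all(keep)) {
    message(sum(!keep), " row(s) with missing values dropped")
    tab <- tab[keep, , drop = FALSE]
  }
  if (nrow(tab) == 0) stop("no complete rows left", call. = FALSE)
  y <- tab[[response]]
  if (!is.numeric(y)) stop("response column must be numeric", call. = FALSE)
  if (length(unique(y)) == 1) stop("response is constant", call. = FALSE)

  X <- matrix(1, nrow(tab), 1, dimnames = list(NULL, "(Intercept)"))
  for (v in fixed) {
    col <- tab[[v]]
    if (is.numeric(col)) {
      X <- cbind(X, matrix(col, dimnames = list(NULL, v)))
    } else {
      # dummy coding, baseline = first observed level
      levs <- unique(col)
      for (lv in levs[-1]) {
        X <- cbind(X, matrix(as.numeric(col == lv),
                             dimnames = list(NULL, paste0(v, lv))))
      }
    }
  }
  grouped_data(y, X, tab[[group]])
}

#' Serialize a fitted model to JSON
#'
#' Writes all numeric components of an `"mqrefit"` at full precision so a
#' round trip reproduces the parameters exactly.
#'
#' @param fit An `"mqrefit"` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @seealso [read_fit_json()]
#' @export
write_fit_json <- function(fit, path) {
  stopifnot(inherits(fit, "mqrefit"))
  obj <- list(
    spec = unclass(fit$spec),
    coefficients = as.list(fit$coefficients),
    varcomp = as.list(fit$varcomp),
    ranef = if (is.null(fit$ranef)) NULL else as.list(fit$ranef),
    scale = fit$scale,
    offset = fit$offset,
    vcov = if (is.null(fit$vcov)) NULL else unname(as.list(as.data.frame(fit$vcov))),
    eq_norms = as.list(fit$eq_norms),
    iterations = fit$iterations,
    converged = fit$converged,
    boundary = fit$boundary,
    n = fit$n, d = fit$d
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Read a fitted model serialized by [write_fit_json()]
#'
#' @param path Path to the JSON file.
#' @return A list mirroring the serialized `"mqrefit"` components (the
#'   numeric parameters are restored exactly; the object is not a full
#'   refittable `"mqrefit"`).
#' @export
read_fit_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$coefficients <- unlist(obj$coefficients)
  obj$varcomp <- unlist(obj$varcomp)
  if (!is.null(obj$ranef)) obj$ranef <- unlist(obj$ranef)
  if (!is.null(obj$vcov)) {
    obj$vcov <- if (is.list(obj$vcov)) do.call(cbind, obj$vcov) else
      as.matrix(obj$vcov)
    dimnames(obj$vcov) <- NULL
  }
  obj$eq_norms <- unlist(obj$eq_norms)
  obj
}
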