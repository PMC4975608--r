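#' Single-level M-quantile regression
#'
#' Fits the linear M-quantile regression model for independent
#' observations: the coefficient vector `beta_q` solves the estimating
#' equation `sum_i psi_q(r_i) x_i = 0` with `r_i = y_i - x_i' beta_q`,
#' where `psi_q` is the asymmetric Huber influence function evaluated at
#' the MAD-standardized residual (see [asym_psi()]).  Estimation is by
#' iterative weighted least squares with the scale re-estimated by
#' [mad_scale()] at each iteration.  For a monotone influence function
#' (Huber with `c > 0`, or squared loss) the solution is unique, so the
#' ordinary least-squares start is immaterial.
#'
#' @param X Design matrix (`n x p`), full column rank, including the
#'   intercept column if one is wanted.
#' @param y Numeric response vector of length `n > p`.
#' @param spec An [mq_spec()] giving `q`, `c` and the loss family.
#' @param control List of solver options; see [mq_control()].
#' @return An object of class `"mqfit"`: a list with `coefficients`,
#'   `scale` (final MAD scale), `residuals`, `fitted`, `weights` (final
#'   IWLS weights), `iterations`, `converged`, `score` (final value of the
#'   estimating equation, one entry per column of `X`) and `spec`.
#' @examples
#' set.seed(1)
#' x <- runif(50, 0, 10)
#' y <- 1 + 2 * x + rnorm(50)
#' fit <- fit_mq(cbind(1, x), y, mq_spec(0.75))
#' coef(fit)
#' @export
fit_mq <- function(X, y, spec = mq_spec(), control = mq_control()) {
  spec <- as_mq_spec(spec)
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- length(y); p <- ncol(X)
  if (nrow(X) != n) stop("nrow(X) must equal length(y)", call. = FALSE)
  if (n <= p) stop("need more observations than columns in X", call. = FALSE)
  qrX <- qr(X)
  if (qrX$rank < p) stop("design matrix is rank deficient", call. = FALSE)

  beta <- qr.coef(qrX, y)
  obj_old <- Inf
  converged <- FALSE
  q <- spec$q
  for (it in seq_len(control$maxit)) {
    r <- drop(y - X %*% beta)
    s <- mad_scale(r)
    w <- asym_psi(r, spec, s) / (r / s)
    w[abs(r) < 1e-300] <- 2 * (1 - q)   # continuity limit at r = 0
    sw <- sqrt(w)
    beta_new <- qr.coef(qr(X * sw), y * sw)
    obj <- sum(asym_rho(r / s, spec))
    dbeta <- max(abs(beta_new - beta))
    dobj <- if (is.finite(obj_old))
      abs(obj - obj_old) / max(abs(obj_old), 1e-12) else Inf
    beta <- beta_new
    obj_old <- obj
    if (dbeta < control$beta_tol && dobj < control$obj_tol) {
      converged <- TRUE
      break
    }
  }
  r <- drop(y - X %*% beta)
  s <- mad_scale(r)
  structure(list(
    coefficients = drop(beta),
    scale = s,
    residuals = r,
    fitted = drop(X %*% beta),
    weights = w,
    iterations = it,
    converged = converged,
    score = drop(crossprod(X, asym_psi(r, spec, s))),
    spec = spec
  ), class = "mqfit")
}

#' Solver options for [fit_mq()]
#'
#' @param maxit Maximum number of IWLS iterations.
#' @param beta_tol Convergence threshold on the max absolute coefficient
#'   change between iterations.
#' @param obj_tol Convergence threshold on the relative change in the
#'   asymmetric-loss objective.
#' @return A list of options.
#' @export
mq_control <- function(maxit = 200, beta_tol = 1e-6, obj_tol = 1e-8) {
  list(maxit = maxit, beta_tol = beta_tol, obj_tol = obj_tol)
}

#' @export
print.mqfit <- function(x, ...) {
  cat(sprintf("Single-level M-quantile fit (q = %g, c = %g, loss = %s)\n",
              x$spec$q, x$spec$c, x$spec$loss))
  cat("Coefficients:\n")
  print(x$coefficients)
  cat(sprintf("MAD scale: %.4g; %d iterations (%s)\n", x$scale,
              x$iterations,
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' @export
coef.mqfit <- function(object, ...) object$coefficients
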