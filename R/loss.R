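#' Specify the target M-quantile
#'
#' An M-quantile specification bundles the order `q` of the target location
#' parameter, the Huber tuning constant `c`, and the loss family.  With the
#' Huber loss the estimator interpolates between expectile regression
#' (large `c`) and quantile-like regression (small positive `c`); `c` must be
#' strictly positive, so exact quantile regression is outside the family.
#' The squared loss is the expectile limit and ignores `c`.
#'
#' @param q Order of the M-quantile, strictly inside (0, 1).  `q = 0.5`
#'   targets a robust centre of the conditional distribution.
#' @param c Huber tuning constant, strictly positive.  The default 1.345
#'   gives 95% Gaussian efficiency for symmetric M-estimation.
#' @param loss `"huber"` or `"squared"`.
#' @return An object of class `"mq_spec"` with elements `q`, `c`, `loss`.
#' @examples
#' mq_spec(0.75)
#' mq_spec(0.5, loss = "squared")  # ordinary squared loss
#' @export
mq_spec <- function(q = 0.5, c = 1.345, loss = c("huber", "squared")) {
  loss <- match.arg(loss)
  if (!is.numeric(q) || length(q) != 1L || is.na(q) || q <= 0 || q >= 1)
    stop("'q' must be a single number strictly inside (0, 1)", call. = FALSE)
  if (!is.numeric(c) || length(c) != 1L || is.na(c) || c <= 0)
    stop("'c' must be a single strictly positive number", call. = FALSE)
  structure(list(q = q, c = c, loss = loss), class = "mq_spec")
}

#' @export
print.mq_spec <- function(x, ...) {
  cat(sprintf("M-quantile spec: q = %g, c = %g, loss = %s\n",
              x$q, x$c, x$loss))
  invisible(x)
}

as_mq_spec <- function(spec) {
  if (inherits(spec, "mq_spec")) return(spec)
  if (is.list(spec)) return(do.call(mq_spec, spec))
  stop("'spec' must be an 'mq_spec' object (see mq_spec())", call. = FALSE)
}

#' Huber influence function
#'
#' The bounded influence function `psi(u) = u` for `|u| <= c` and
#' `c * sign(u)` beyond, the derivative of the Huber loss.
#'
#' @param u Numeric vector of standardized residuals.
#' @param c Tuning constant, strictly positive.
#' @return Numeric vector, elementwise clamped to `[-c, c]`.
#' @examples
#' huber_psi(c(-3, -0.5, 0, 2), 1.345)
#' @export
huber_psi <- function(u, c = 1.345) {
  if (!is.numeric(c) || length(c) != 1L || is.na(c) || c <= 0)
    stop("'c' must be a single strictly positive number", call. = FALSE)
  pmin(pmax(u, -c), c)
}

# asymmetric weight 2q / 2(1-q) by the sign of the residual; the u <= 0
# branch carries 2(1-q), matching the loss definition at the origin
asym_weight <- function(u, q) 2 * ifelse(u > 0, q, 1 - q)

#' Asymmetric Huber influence function
#'
#' The q-specific influence function
#' `psi_q(u) = 2 psi(u / s) * (q I(u > 0) + (1 - q) I(u <= 0))`,
#' where `psi` is the Huber function with tuning constant `c` and `s > 0`
#' is a scale.  At `q = 0.5` it reduces to the symmetric Huber function of
#' `u / s`.  For the squared loss, `psi_q(u) = 2 u (q or 1 - q)` and `s`
#' rescales the argument.
#'
#' @param u Numeric vector of residuals.
#' @param spec An [mq_spec()].
#' @param s Positive scale estimate applied to `u` before clamping.
#' @return Numeric vector of influence values.
#' @examples
#' asym_psi(1, mq_spec(0.75), s = 1)    # 2 * min(1, c) * 0.75 = 1.5
#' asym_psi(-1, mq_spec(0.75), s = 1)   # 2 * (-1) * 0.25 = -0.5
#' @export
asym_psi <- function(u, spec, s = 1) {
  spec <- as_mq_spec(spec)
  if (!is.numeric(s) || length(s) != 1L || is.na(s) || s <= 0)
    stop("'s' must be a single strictly positive scale", call. = FALSE)
  w <- asym_weight(u, spec$q)
  if (spec$loss == "squared") w * (u / s) else w * huber_psi(u / s, spec$c)
}

#' Asymmetric Huber loss
#'
#' The loss whose derivative (at unit scale) is [asym_psi()]:
#' `rho_q(u) = u^2 w(u)` for `|u| <= c` and `(2 c |u| - c^2) w(u)` beyond,
#' with `w(u) = q I(u > 0) + (1 - q) I(u <= 0)`.  For the squared loss the
#' quadratic branch applies everywhere.
#'
#' @inheritParams asym_psi
#' @return Numeric vector of nonnegative loss values, zero only at `u = 0`.
#' @examples
#' asym_rho(1, mq_spec(0.75))  # inside the core: 1^2 * 0.75
#' @export
asym_rho <- function(u, spec) {
  spec <- as_mq_spec(spec)
  w <- ifelse(u > 0, spec$q, 1 - spec$q)
  if (spec$loss == "squared") return(u^2 * w)
  cc <- spec$c
  ifelse(abs(u) <= cc, u^2, 2 * cc * abs(u) - cc^2) * w
}

# a.e. derivative of asym_psi in u (used for Newton steps)
asym_psi_deriv <- function(u, spec, s = 1) {
  w <- asym_weight(u, spec$q)
  if (spec$loss == "squared") w / s else w * (abs(u / s) <= spec$c) / s
}

#' Median-absolute-deviation scale of residuals
#'
#' `s = median(|r|) / 0.6745`, the scale estimate used inside the
#' M-quantile estimating equations.  The constant 0.6745 makes `s`
#' consistent for the standard deviation at the Gaussian model.
#'
#' @param residuals Numeric vector with at least one nonzero element.
#' @return A single positive number.
#' @examples
#' mad_scale(c(-1, 0, 1))  # 1 / 0.6745
#' @export
mad_scale <- function(residuals) {
  if (!is.numeric(residuals) || length(residuals) == 0L)
    stop("'residuals' must be a non-empty numeric vector", call. = FALSE)
  s <- stats::median(abs(residuals)) / 0.6745
  if (!is.finite(s) || s <= 0)
    stop("degenerate residual scale: median absolute residual is zero",
         call. = FALSE)
  s
}
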