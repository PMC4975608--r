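#' Sandwich covariance of the q-specific fixed effects
#'
#' First-order (Taylor) covariance estimator
#' `A^{-1} B A^{-T}` for the fixed effects of an M-quantile
#' random-effects fit.  The bread `A` is the observed derivative of the
#' fixed-effects estimating equation,
#' `A = X' V^{-1} diag(psi_q'(r_q)) X`, with the influence slope
#' evaluated at the fitted scaled residuals (so the actual clamping
#' fraction of the data, not a Gaussian reference, sets the
#' sensitivity).  The middle `B` is the empirical second moment of the
#' group-level score contributions `g_j = X_j' V_j^{-1} U_j^{1/2}
#' psi_q(r_j)`, which captures the within-group dependence of the scores,
#' with the usual small-`d` degrees-of-freedom correction `d / (d - 1)`.
#' Uncertainty in the variance components is not propagated (plug-in
#' estimator).
#'
#' @param fit A converged `"mqrefit"` object.
#' @param data The [grouped_data()] object the model was fitted to.
#' @return A symmetric positive semidefinite `p x p` matrix.
#' @export
beta_covariance <- function(fit, data) {
  stopifnot(inherits(fit, "mqrefit"), inherits(data, "grouped_data"))
  if (!fit$converged)
    stop("covariance requires a converged fit", call. = FALSE)
  spec <- fit$spec
  sg <- fit$varcomp[["sigma2_gamma"]]
  se <- fit$varcomp[["sigma2_eps"]]
  u <- sg + se
  r <- drop(data$y - data$X %*% fit$coefficients) / sqrt(u)
  a <- vinv_mat(matrix(sqrt(u) * asym_psi(r, spec, fit$scale), ncol = 1),
                data$group, data$sizes, sg, se)[, 1]
  G <- rowsum(a * data$X, data$group, reorder = TRUE)    # d x p group scores
  d <- data$d
  B <- crossprod(G) * d / (d - 1)
  w <- asym_psi_deriv(r, spec, fit$scale)
  A <- crossprod(data$X,
                 vinv_mat(w * data$X, data$group, data$sizes, sg, se))
  Ainv <- solve(A)
  V <- Ainv %*% B %*% t(Ainv)
  dimnames(V) <- list(colnames(data$X), colnames(data$X))
  (V + t(V)) / 2
}

#' Coefficient table across a grid of M-quantile orders
#'
#' Collects estimates, standard errors and normal-approximation
#' confidence intervals from a list of fits at different `q`, in long
#' format -- the numerical content of coefficient-versus-q profile plots.
#'
#' @param fits A non-empty list of converged `"mqrefit"` objects sharing
#'   the same design (same coefficient names).
#' @param alpha Two-sided error level of the confidence intervals.
#' @return A data frame with columns `q`, `term`, `estimate`, `se`,
#'   `lower`, `upper`.
#' @examples
#' \dontrun{
#' fits <- lapply(c(0.25, 0.5, 0.75), function(q)
#'   fit_mqre(dat, mq_spec(q)))
#' coefficient_table(fits)
#' }
#' @export
coefficient_table <- function(fits, alpha = 0.05) {
  if (length(fits) == 0) stop("empty fit list", call. = FALSE)
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)", call. = FALSE)
  terms0 <- names(fits[[1]]$coefficients)
  z <- stats::qnorm(1 - alpha / 2)
  rows <- lapply(fits, function(f) {
    stopifnot(inherits(f, "mqrefit"))
    if (!identical(names(f$coefficients), terms0))
      stop("all fits must share a common design", call. = FALSE)
    se <- sqrt(diag(if (is.null(f$vcov)) stop("fit lacks vcov") else f$vcov))
    data.frame(q = f$spec$q, term = terms0, estimate = unname(f$coefficients),
               se = unname(se), lower = unname(f$coefficients - z * se),
               upper = unname(f$coefficients + z * se))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
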