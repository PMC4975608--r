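#' Scaled residuals of the random-intercepts M-quantile model
#'
#' `r_q = U^{-1/2} (y - X beta)`, where `U = diag(V)` holds the marginal
#' variances `sigma2_gamma + sigma2_eps` of the two-level model.
#'
#' @param data A [grouped_data()] object.
#' @param beta Fixed-effects coefficient vector.
#' @param sigma2_gamma,sigma2_eps Variance components.
#' @return Numeric vector of length `n`.
#' @export
scaled_residuals <- function(data, beta, sigma2_gamma, sigma2_eps) {
  stopifnot(inherits(data, "grouped_data"))
  u <- sigma2_gamma + sigma2_eps
  if (u <= 0) stop("total variance must be positive", call. = FALSE)
  drop(data$y - data$X %*% beta) / sqrt(u)
}

#' Control options for [fit_mqre()]
#'
#' @param maxit Maximum outer iterations (one beta solve plus one
#'   variance-component sweep each).
#' @param beta_maxit Maximum Newton-Raphson iterations per inner beta
#'   solve.
#' @param beta_tol Inner convergence threshold on the max absolute Newton
#'   step.
#' @param param_tol Outer convergence threshold on the max relative
#'   parameter change.
#' @param eq_tol Per-observation tolerance on the estimating-equation
#'   norms: at convergence all three left-hand sides are below
#'   `eq_tol * n` in absolute value.
#' @param var_floor Lower bound for the variance components.  A
#'   level-2 component pushed to the floor is reported as a boundary
#'   estimate.
#' @param fix_varcomp Optional numeric vector
#'   `c(sigma2_gamma, sigma2_eps)`: hold the variance components fixed and
#'   only solve for the fixed effects.
#' @param ranef Logical: predict the random effects after convergence.
#' @param cov Logical: compute the sandwich covariance of the fixed
#'   effects after convergence.
#' @return A list of options.
#' @export
mqre_control <- function(maxit = 500, beta_maxit = 80, beta_tol = 1e-9,
                         param_tol = 1e-5, eq_tol = 1e-6,
                         var_floor = 1e-6, fix_varcomp = NULL,
                         ranef = TRUE, cov = TRUE) {
  list(maxit = maxit, beta_maxit = beta_maxit, beta_tol = beta_tol,
       param_tol = param_tol, eq_tol = eq_tol, var_floor = var_floor,
       fix_varcomp = fix_varcomp, ranef = ranef, cov = cov)
}

# influence values of the beta equation: psi_q at MAD scale s (huber) or
# unit scale (squared)
.psi_beta <- function(r, spec, s) asym_psi(r, spec, s)

# score of the beta equation and its V^{-1}-weighted influence vector a:
# score = X' a with a = V^{-1} U^{1/2} psi_q(r_q)
.mqre_score <- function(data, beta, sg, se, spec, s) {
  u <- sg + se
  r <- drop(data$y - data$X %*% beta) / sqrt(u)
  a <- vinv_mat(matrix(sqrt(u) * .psi_beta(r, spec, s), ncol = 1),
                data$group, data$sizes, sg, se)[, 1]
  list(r = r, a = a, score = drop(crossprod(data$X, a)))
}

# One damped Newton-Raphson step for the fixed effects.  The Jacobian of
# the score is -X' V^{-1} W X with W = diag(psi_q'(r_q)) (U^{1/2} and
# U^{-1/2} cancel because U is a scalar multiple of the identity here).
# Step halving enforces a decrease of the score norm; a singular Jacobian
# gets a small ridge.
beta_step <- function(data, beta, sg, se, spec, s, state = NULL) {
  if (is.null(state)) state <- .mqre_score(data, beta, sg, se, spec, s)
  w <- asym_psi_deriv(state$r, spec, s)
  J <- crossprod(data$X, vinv_mat(w * data$X, data$group, data$sizes, sg, se))
  step <- tryCatch(solve(J, state$score), error = function(e) {
    solve(J + diag(1e-8 * (1 + abs(diag(J))), nrow(J)), state$score)
  })
  lam <- 1
  repeat {
    cand <- beta + lam * step
    st_new <- .mqre_score(data, cand, sg, se, spec, s)
    if (sum(st_new$score^2) <= sum(state$score^2) || lam < 1e-8) break
    lam <- lam / 2
  }
  list(beta = beta + lam * step, state = st_new,
       step_size = max(abs(lam * step)))
}

# One proportional fixed-point sweep for the variance components.  The
# symmetric Huber influence (clamp c) is applied to the scaled residuals
# recentred by the normal-reference offset z_q; K2 = E[huber_psi(Z, c)^2]
# calibrates both equations.  Updates are multiplicative, hence
# positivity preserving, and stationary exactly at roots of the
# estimating equations.
variance_step <- function(data, r, sg, se, spec, zq, k2) {
  u <- sg + se
  v <- if (spec$loss == "squared") r + zq else huber_psi(r + zq, spec$c)
  a <- vinv_mat(matrix(sqrt(u) * v, ncol = 1),
                data$group, data$sizes, sg, se)[, 1]
  gs <- as.numeric(rowsum(a, data$group, reorder = TRUE))
  denom <- se + data$sizes * sg
  tr_zzt <- sum(data$sizes / denom)
  tr_inv <- sum((data$sizes - 1) / se + 1 / denom)
  list(
    sigma2_gamma = sg * sum(gs^2) / (k2 * tr_zzt),
    sigma2_eps = se * sum(a^2) / (k2 * tr_inv),
    eq_gamma = 0.5 * sum(gs^2) - 0.5 * k2 * tr_zzt,
    eq_eps = 0.5 * sum(a^2) - 0.5 * k2 * tr_inv
  )
}

#' Fit the M-quantile random-effects regression model
#'
#' Fits a two-level random-intercepts M-quantile regression: the q-th
#' M-quantile of the conditional distribution of the response is modelled
#' as `x' beta_q + gamma_j`, with a group-specific random intercept and
#' q-specific variance components `sigma2_gamma` (level 2) and
#' `sigma2_eps` (level 1).  Estimation solves robust estimating equations:
#' the fixed effects by damped Newton-Raphson applied to
#' `X' V^{-1} U^{1/2} psi_q(r_q) = 0`, where `r_q` are the scaled
#' residuals and `psi_q` the asymmetric Huber influence function at MAD
#' scale, and the variance components by a positivity-preserving
#' fixed-point iteration on the Huber-proposal-2-type second-moment
#' equations, evaluated on the scaled residuals recentred by the
#' normal-reference M-quantile offset.  At `q = 0.5` with squared loss the
#' procedure reproduces Gaussian maximum likelihood for the
#' random-intercepts model; at `q = 0.5` with Huber loss it is a robust
#' ML estimator of Huber-proposal-2 type; with squared loss at other `q`
#' it is expectile random-effects regression.
#'
#' @param data A [grouped_data()] object with at least two groups.
#' @param spec An [mq_spec()].
#' @param control A list from [mqre_control()].
#' @return An object of class `"mqrefit"`: list with `coefficients`,
#'   `varcomp` (named vector `sigma2_gamma`, `sigma2_eps`), `ranef`
#'   (predicted random effects, or `NULL`), `scaled_residuals`, `scale`
#'   (MAD scale of the scaled residuals), `offset` (normal-reference
#'   recentring offset `z_q`), `vcov` (sandwich covariance of the fixed
#'   effects, or `NULL`), `eq_norms` (absolute values of the three
#'   estimating-equation left-hand sides at the solution), `iterations`,
#'   `converged`, `boundary` (`TRUE` if the level-2 variance was clamped
#'   at the floor), `spec`, `control`, and the dimensions `n`, `d`.
#' @seealso [fit_expectile_re()], [predict_ranef()], [beta_covariance()]
#' @examples
#' set.seed(7)
#' g <- rep(1:20, each = 6)
#' x <- runif(120, 0, 10)
#' y <- 2 + x + rnorm(20)[g] + rnorm(120)
#' fit <- fit_mqre(grouped_data(y, cbind(1, x), g), mq_spec(0.5))
#' coef(fit); fit$varcomp
#' @export
fit_mqre <- function(data, spec = mq_spec(), control = mqre_control()) {
  stopifnot(inherits(data, "grouped_data"))
  spec <- as_mq_spec(spec)
  if (data$d < 2) stop("need at least two groups", call. = FALSE)
  if (data$n <= data$p) stop("need n > p", call. = FALSE)
  q <- spec$q
  k2 <- k2_symmetric(spec$c, spec$loss)
  floor_ <- control$var_floor
  fixed_vc <- !is.null(control$fix_varcomp)

  # starting values: single-level M-quantile fit, then a robust moment
  # decomposition of its raw residuals
  init <- fit_mq(data$X, data$y, spec)
  beta <- init$coefficients
  res <- init$residuals
  if (fixed_vc) {
    sg <- control$fix_varcomp[[1]]
    se <- control$fix_varcomp[[2]]
    if (se <= 0) stop("fixed sigma2_eps must be > 0", call. = FALSE)
    sg <- max(sg, 0)
  } else {
    gmeans <- as.numeric(rowsum(res, data$group, reorder = TRUE)) / data$sizes
    within <- res - gmeans[data$group]
    se <- max(floor_, stats::median(abs(within))^2 / 0.6745^2)
    sg <- max(floor_, stats::var(gmeans) - se / mean(data$sizes))
  }

  s <- 1; zq <- 0
  converged <- FALSE
  boundary <- FALSE
  eq <- c(score = Inf, eq_gamma = Inf, eq_eps = Inf)
  for (it in seq_len(control$maxit)) {
    beta_old <- beta; sg_old <- sg; se_old <- se
    u <- sg + se
    r <- drop(data$y - data$X %*% beta) / sqrt(u)
    if (spec$loss == "huber") s <- mad_scale(r)
    zq <- normal_mq_offset(q, spec$c, s, spec$loss)

    # inner Newton-Raphson solve for the fixed effects
    state <- .mqre_score(data, beta, sg, se, spec, s)
    for (nit in seq_len(control$beta_maxit)) {
      stp <- beta_step(data, beta, sg, se, spec, s, state)
      beta <- stp$beta; state <- stp$state
      if (stp$step_size < control$beta_tol) break
    }

    vs <- variance_step(data, state$r, sg, se, spec, zq, k2)
    if (!fixed_vc) {
      sg_new <- vs$sigma2_gamma
      if (sg_new < floor_) { sg_new <- floor_; boundary <- TRUE }
      se <- max(floor_, vs$sigma2_eps)
      sg <- sg_new
    }
    eq <- c(score = max(abs(state$score)),
            eq_gamma = abs(vs$eq_gamma), eq_eps = abs(vs$eq_eps))

    rel <- max(abs(c(beta - beta_old, sg - sg_old, se - se_old)) /
                 pmax(abs(c(beta_old, sg_old, se_old)), 1e-3))
    eq_ok <- if (fixed_vc) eq[["score"]] < control$eq_tol * data$n else
      max(eq) < control$eq_tol * data$n
    if (rel < control$param_tol && eq_ok) { converged <- TRUE; break }
  }
  if (boundary && !fixed_vc)
    warning("level-2 variance clamped at the floor (boundary estimate)",
            call. = FALSE)
  if (!converged)
    warning(sprintf("fit_mqre did not converge in %d outer iterations",
                    control$maxit), call. = FALSE)

  fit <- structure(list(
    coefficients = stats::setNames(drop(beta), colnames(data$X)),
    varcomp = c(sigma2_gamma = sg, sigma2_eps = se),
    ranef = NULL,
    scaled_residuals = drop(data$y - data$X %*% beta) / sqrt(sg + se),
    scale = s,
    offset = zq,
    vcov = NULL,
    eq_norms = eq,
    iterations = it,
    converged = converged,
    boundary = boundary,
    spec = spec,
    control = control,
    n = data$n, d = data$d
  ), class = "mqrefit")
  if (control$cov && converged)
    fit$vcov <- beta_covariance(fit, data)
  if (control$ranef)
    fit$ranef <- predict_ranef(fit, data)
  fit
}

#' Expectile random-effects regression
#'
#' The squared-loss special case of [fit_mqre()]: for `q != 0.5` this is
#' expectile random-effects regression, and at `q = 0.5` it coincides
#' with the Gaussian maximum-likelihood fit of the random-intercepts
#' model.
#'
#' @param data A [grouped_data()] object.
#' @param q Expectile order in (0, 1).
#' @param control See [mqre_control()].
#' @return An `"mqrefit"` object; see [fit_mqre()].
#' @export
fit_expectile_re <- function(data, q = 0.5, control = mqre_control()) {
  fit_mqre(data, mq_spec(q, c = 1.345, loss = "squared"), control)
}

#' @export
print.mqrefit <- function(x, ...) {
  cat(sprintf("M-quantile random-effects fit (q = %g, c = %g, loss = %s)\n",
              x$spec$q, x$spec$c, x$spec$loss))
  cat(sprintf("n = %d observations in d = %d groups\n", x$n, x$d))
  cat("Fixed effects:\n")
  if (!is.null(x$vcov)) {
    tab <- cbind(Estimate = x$coefficients,
                 `Std. Error` = sqrt(diag(x$vcov)))
    print(round(tab, 4))
  } else print(x$coefficients)
  cat(sprintf("Variance components: sigma2_gamma = %.4g, sigma2_eps = %.4g\n",
              x$varcomp[["sigma2_gamma"]], x$varcomp[["sigma2_eps"]]))
  cat(sprintf("%d outer iterations (%s)%s\n", x$iterations,
              if (x$converged) "converged" else "NOT converged",
              if (x$boundary) "; level-2 variance at boundary" else ""))
  invisible(x)
}

#' @export
coef.mqrefit <- function(object, ...) object$coefficients

#' @export
vcov.mqrefit <- function(object, ...) object$vcov
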