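#' Second moment of the asymmetric influence function at the standard normal
#'
#' Computes `K2q = E[psi_q(Z)^2]` for `Z ~ N(0, 1)`, where `psi_q` is the
#' asymmetric influence function of [asym_psi()] at unit scale.  For the
#' Huber loss the closed form is
#' `K2q = 4 (q^2 + (1 - q)^2) * A(c)` with
#' `A(c) = Phi(c) - 1/2 - c phi(c) + c^2 (1 - Phi(c))` the per-tail
#' truncated second moment; for the squared loss
#' `K2q = 2 (q^2 + (1 - q)^2)`.  At `q = 0.5` with large `c` the value
#' tends to 1 (the variance of `Z`).  The constant is symmetric in
#' `q <-> 1 - q`.
#'
#' @param q M-quantile order in (0, 1).
#' @param c Huber tuning constant, `> 0`.
#' @param loss `"huber"` or `"squared"`.
#' @return An object of class `"k2_constant"`: list with `q`, `c`, `loss`
#'   and `value`.
#' @examples
#' k2q(0.5, 1.345)$value   # about 0.7101
#' k2q(0.5, 1e6)$value     # about 1
#' @export
k2q <- function(q, c = 1.345, loss = c("huber", "squared")) {
  loss <- match.arg(loss)
  spec <- mq_spec(q, c, loss)  # validates q and c
  value <- if (loss == "squared") {
    2 * (q^2 + (1 - q)^2)
  } else {
    4 * (q^2 + (1 - q)^2) * huber_tail_m2(c)
  }
  structure(list(q = q, c = c, loss = loss, value = value),
            class = "k2_constant")
}

#' @export
print.k2_constant <- function(x, ...) {
  cat(sprintf("K2(q = %g, c = %g, %s) = %.6f\n", x$q, x$c, x$loss, x$value))
  invisible(x)
}

# E[huber_psi(Z, c)^2 I(Z > 0)] for Z ~ N(0,1): truncated second moment of
# one tail plus the clamped mass
huber_tail_m2 <- function(c) {
  stats::pnorm(c) - 0.5 - c * stats::dnorm(c) + c^2 * (1 - stats::pnorm(c))
}

# E[huber_psi(Z, c)^2], Z ~ N(0,1): symmetric-psi calibration constant used
# by the variance-component estimating equations
k2_symmetric <- function(c, loss) {
  if (loss == "squared") 1 else 2 * huber_tail_m2(c)
}

# E[(Z - z)^2 I(a < Z < b)] building block: int_a^b (x - z)^2 phi(x) dx
.norm_m2_shift <- function(a, b, z) {
  pa <- stats::pnorm(a); pb <- stats::pnorm(b)
  da <- stats::dnorm(a); db <- stats::dnorm(b)
  (pb - pa) + a * da - b * db - 2 * z * (da - db) + z^2 * (pb - pa)
}

# E[psi_q((Z - z)/s)] for Z ~ N(0,1): closed-form normal expectation of the
# asymmetric influence function about a shifted centre
asym_psi_normal_mean <- function(z, q, c, s, loss) {
  if (loss == "squared") {
    # E[(Z - z) I(Z > z)] = phi(z) - z (1 - Phi(z)); lower tail analogous
    up <- stats::dnorm(z) - z * (1 - stats::pnorm(z))
    lo <- -stats::dnorm(z) - z * stats::pnorm(z)
    return(2 * q * up + 2 * (1 - q) * lo)
  }
  cs <- c * s
  ipart <- function(a, b) {
    stats::dnorm(a) - stats::dnorm(b) - z * (stats::pnorm(b) - stats::pnorm(a))
  }
  2 * q * (ipart(z, z + cs) / s + c * (1 - stats::pnorm(z + cs))) +
    2 * (1 - q) * (ipart(z - cs, z) / s - c * stats::pnorm(z - cs))
}

# Normal-reference M-quantile offset: the root z_q of
# E[psi_q((Z - z)/s)] = 0, Z ~ N(0,1).  Fitted residuals about the q-th
# M-quantile surface are centred near -z_q on the standardized scale, so
# adding z_q recentres them at the Gaussian core.  z_{0.5} = 0 exactly.
normal_mq_offset <- function(q, c, s = 1, loss = "huber") {
  if (abs(q - 0.5) < 1e-14) return(0)
  f <- function(z) asym_psi_normal_mean(z, q, c, s, loss)
  stats::uniroot(f, lower = -10, upper = 10, extendInt = "downX",
                 tol = 1e-12)$root
}

# E[psi_q'((Z - z)/s) * d/dr] evaluated at the shifted normal reference:
# expected slope of the beta-equation influence term, used in the
# sandwich 'bread' matrix
asym_psi_normal_dmean <- function(z, q, c, s, loss) {
  if (loss == "squared") {
    return(2 * (q * (1 - stats::pnorm(z)) + (1 - q) * stats::pnorm(z)) / s)
  }
  cs <- c * s
  (2 / s) * (q * (stats::pnorm(z + cs) - stats::pnorm(z)) +
               (1 - q) * (stats::pnorm(z) - stats::pnorm(z - cs)))
}
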