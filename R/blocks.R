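#' Block covariance operator for the random-intercepts model
#'
#' The marginal covariance of a two-level random-intercepts model is block
#' diagonal: per group `j` of size `n_j`,
#' `V_j = sigma2_eps I + sigma2_gamma 1 1'`.  This constructor returns an
#' operator object exploiting the rank-one structure (Sherman-Morrison),
#' so no `n x n` matrix is ever materialized: solves, log-determinant,
#' diagonal and quadratic forms all cost O(n).
#'
#' @param sigma2_gamma Level-2 (between-group) variance, `>= 0`.
#' @param sigma2_eps Level-1 (within-group) variance, `> 0`.
#' @param sizes Integer vector of group sizes `n_j`.
#' @return A list with fields `sigma2_gamma`, `sigma2_eps`, `sizes`, `n`,
#'   `udiag` (the common diagonal element of V), `logdet`, and functions
#'   `solve(v)` (returns `V^{-1} v` for a vector ordered by group),
#'   `mult(v)` (returns `V v`), `trace_inv()` (`tr(V^{-1})`) and
#'   `trace_inv_zzt()` (`tr(V^{-1} Z Z')` with Z the group-indicator
#'   matrix).
#' @examples
#' op <- build_covariance(2, 1, sizes = c(2, 1))
#' op$udiag             # 3
#' op$solve(c(1, 0, 1)) # blockwise inverse times vector
#' @export
build_covariance <- function(sigma2_gamma, sigma2_eps, sizes) {
  if (sigma2_eps <= 0) stop("'sigma2_eps' must be > 0", call. = FALSE)
  if (sigma2_gamma < 0) stop("'sigma2_gamma' must be >= 0", call. = FALSE)
  sizes <- as.integer(sizes)
  if (any(sizes < 1L)) stop("all group sizes must be >= 1", call. = FALSE)
  g <- rep.int(seq_along(sizes), sizes)
  n <- sum(sizes)
  sg <- sigma2_gamma; se <- sigma2_eps
  denom <- se + sizes * sg              # per-group se + n_j sg
  list(
    sigma2_gamma = sg, sigma2_eps = se, sizes = sizes, n = n,
    udiag = se + sg,
    logdet = sum((sizes - 1) * log(se) + log(denom)),
    solve = function(v) {
      gs <- rowsum_by(v, g, length(sizes))
      v / se - (sg / (se * denom))[g] * gs[g]
    },
    mult = function(v) {
      gs <- rowsum_by(v, g, length(sizes))
      se * v + sg * gs[g]
    },
    trace_inv = function() sum((sizes - 1) / se + 1 / denom),
    trace_inv_zzt = function() sum(sizes / denom)
  )
}

# fast single-column rowsum
rowsum_by <- function(v, g, d) {
  as.numeric(rowsum(v, g, reorder = TRUE))
}

# V^{-1} applied columnwise to a matrix, for group index g with sizes nj
vinv_mat <- function(M, g, nj, sg, se) {
  gs <- rowsum(M, g, reorder = TRUE)[g, , drop = FALSE]
  M / se - (sg / (se * (se + nj * sg)))[g] * gs
}
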