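#' Monte Carlo scenario definitions
#'
#' Builds the fixed design of the simulation study: `d = 100` groups with
#' sizes drawn uniformly on 5..20 and then repaired to a total of
#' `n = 1259` rows, a single covariate `x1 ~ U[0, 20]`, and the
#' location-shift data-generating model
#' `y_ij = 100 + 2 x1_ij + gamma_j + eps_ij`.  Design quantities (group
#' sizes and `x1`) are held fixed across replicates; only the error draws
#' change.  Four error-generation mechanisms are available:
#' \describe{
#'   \item{`"NN"`}{`gamma ~ N(0, 3)`, `eps ~ N(0, 5)` (model assumptions
#'     hold).}
#'   \item{`"TT"`}{`gamma ~ t(3)`, `eps ~ t(3)` (heavy tails at both
#'     levels; variates unscaled, so the level-1 variance is 3).}
#'   \item{`"NLap"`}{`gamma ~ N(0, 3)`, `eps ~ Laplace(0, scale 1.58)`
#'     (level-1 variance about 5, excess kurtosis 3).}
#'   \item{`"contaminated"`}{`gamma ~ N(0, 3)` for groups 1..90 and
#'     `N(0, 20)` for groups 91..100; `eps ~ 0.9 N(0, 5) + 0.1 N(0, 150)`
#'     (outliers at both levels).}
#' }
#'
#' @param id Scenario identifier, one of `"NN"`, `"TT"`, `"NLap"`,
#'   `"contaminated"`.
#' @param seed Integer seed fixing the design draw.
#' @return An object of class `"mc_scenario"`: list with `id`, `d`, `n`,
#'   `sizes`, `group`, `x1`, `X` (design matrix with intercept), `beta`
#'   (true fixed effects `c(100, 2)`), `seed`.
#' @examples
#' scn <- mc_scenario("NN", seed = 1)
#' scn$n  # 1259
#' @export
mc_scenario <- function(id = c("NN", "TT", "NLap", "contaminated"),
                        seed = 1L) {
  id <- match.arg(id)
  local_seed(seed)
  d <- 100L
  target_n <- 1259L
  sizes <- sample(5:20, d, replace = TRUE)
  # repair the total by nudging randomly chosen groups within [5, 20]
  while (sum(sizes) != target_n) {
    j <- sample.int(d, 1L)
    sizes[j] <- min(20L, max(5L, sizes[j] + sign(target_n - sum(sizes))))
  }
  group <- rep.int(seq_len(d), sizes)
  x1 <- stats::runif(target_n, 0, 20)
  structure(list(
    id = id, d = d, n = target_n, sizes = sizes, group = group,
    x1 = x1, X = cbind(`(Intercept)` = 1, x1 = x1),
    beta = c(100, 2), seed = seed
  ), class = "mc_scenario")
}

#' @export
print.mc_scenario <- function(x, ...) {
  cat(sprintf("Monte Carlo scenario %s: d = %d groups, n = %d, design seed %d\n",
              x$id, x$d, x$n, x$seed))
  invisible(x)
}

#' Draw one replicate dataset from a scenario
#'
#' Generates fresh level-1 and level-2 errors according to the scenario's
#' mechanism and returns the assembled two-level dataset.  The design
#' (group sizes, covariate values) comes from the scenario and is not
#' redrawn.
#'
#' @param scenario An [mc_scenario()] object.
#' @param seed Integer seed for the error draws of this replicate.
#' @return A [grouped_data()] object.
#' @export
mc_draw <- function(scenario, seed) {
  stopifnot(inherits(scenario, "mc_scenario"))
  local_seed(seed)
  d <- scenario$d; n <- scenario$n
  err <- switch(scenario$id,
    NN = list(g = stats::rnorm(d, 0, sqrt(3)),
              e = stats::rnorm(n, 0, sqrt(5))),
    TT = list(g = stats::rt(d, df = 3),
              e = stats::rt(n, df = 3)),
    NLap = list(g = stats::rnorm(d, 0, sqrt(3)),
                e = stats::rexp(n, rate = 1 / 1.58) -
                    stats::rexp(n, rate = 1 / 1.58)),
    contaminated = list(
      g = c(stats::rnorm(90, 0, sqrt(3)), stats::rnorm(10, 0, sqrt(20))),
      e = ifelse(stats::runif(n) < 0.9,
                 stats::rnorm(n, 0, sqrt(5)),
                 stats::rnorm(n, 0, sqrt(150))))
  )
  y <- scenario$beta[1] + scenario$beta[2] * scenario$x1 +
    err$g[scenario$group] + err$e
  grouped_data(y, scenario$X, scenario$group)
}

#' True target parameters of a scenario at order q
#'
#' The bias target is the q-th quantile of the conditional distribution:
#' the slope is 2 for every `q` (location-shift model) and the intercept
#' is `100 + F^{-1}(q)` with `F` the nominal level-1 error distribution.
#' Under contamination the quantile of the uncontaminated `N(0, 5)` core
#' is used.
#'
#' @param scenario An [mc_scenario()] object (or a scenario id string).
#' @param q Quantile order in (0, 1).
#' @return Named numeric vector `c(intercept, slope)`.
#' @examples
#' mc_truth("NN", 0.75)  # intercept 100 + 0.6745 * sqrt(5)
#' @export
mc_truth <- function(scenario, q) {
  id <- if (inherits(scenario, "mc_scenario")) scenario$id else
    match.arg(scenario, c("NN", "TT", "NLap", "contaminated"))
  if (q <= 0 || q >= 1) stop("q must be in (0, 1)", call. = FALSE)
  shift <- switch(id,
    NN = stats::qnorm(q, 0, sqrt(5)),
    TT = stats::qt(q, df = 3),
    NLap = if (q <= 0.5) 1.58 * log(2 * q) else -1.58 * log(2 * (1 - q)),
    contaminated = stats::qnorm(q, 0, sqrt(5))
  )
  c(intercept = 100 + shift, slope = 2)
}

#' Average relative bias (percent)
#'
#' `ARB = 100 * mean((estimate - theta) / theta)` over Monte Carlo
#' replicates.
#'
#' @param estimates Numeric vector of replicate estimates.
#' @param theta True (nonzero) target value.
#' @return A single number, in percent.
#' @export
arb <- function(estimates, theta) {
  if (theta == 0) stop("ARB is undefined for theta = 0", call. = FALSE)
  100 * mean((estimates - theta) / theta)
}

#' Relative efficiency against a reference estimator
#'
#' Ratio of Monte Carlo variances `S2(model) / S2(reference)` with
#' `S2 = mean((x - mean(x))^2)` (the `1/R` convention).  The reference is
#' conventionally the single-level M-quantile estimator.
#'
#' @param model_estimates,reference_estimates Numeric vectors of replicate
#'   estimates (each of length at least 2).
#' @return A single positive number; 1 when the two vectors coincide.
#' @export
eff <- function(model_estimates, reference_estimates) {
  if (length(model_estimates) < 2 || length(reference_estimates) < 2)
    stop("need at least 2 replicates", call. = FALSE)
  s2 <- function(x) mean((x - mean(x))^2)
  ref <- s2(reference_estimates)
  if (ref == 0) stop("reference estimator has zero variance", call. = FALSE)
  s2(model_estimates) / ref
}

#' Run the Monte Carlo evaluation study
#'
#' Replicates each scenario `R` times and, per replicate, fits the
#' requested estimators: `"MQRE"` (M-quantile random effects, Huber loss)
#' at every `q`, `"MQ"` (single-level M-quantile, the efficiency
#' reference) at every `q`, and `"LRE"` (Gaussian ML random-intercepts
#' model, i.e. the `q = 0.5` squared-loss fit) at `q = 0.5` only.
#' Summaries per (scenario, q, estimator, coefficient): mean estimate,
#' empirical standard error (`1/R` convention), mean estimated
#' (sandwich) standard error where available, average relative bias
#' against [mc_truth()], and relative efficiency against MQ.
#' Replicates where a fit fails to converge are excluded for that
#' estimator and counted.
#'
#' @param scenarios Character vector of scenario ids.
#' @param q Numeric vector of M-quantile orders.
#' @param R Number of Monte Carlo replicates (at least 2).
#' @param seed Master seed; design and replicate seeds are derived from
#'   it, so any subset of the study is reproducible.
#' @param estimators Subset of `c("MQRE", "MQ", "LRE")`.
#' @param c Huber tuning constant for MQRE and MQ.
#' @return An object of class `"mc_report"`: a data frame with columns
#'   `scenario`, `q`, `estimator`, `term`, `mean`, `emp_se`, `est_se`,
#'   `arb`, `eff`, `reps_used`, `n_fail`, plus attributes `R`, `seed`,
#'   `c`.
#' @examples
#' \dontrun{
#' rep <- run_mc_study("NN", q = 0.5, R = 50, seed = 1)
#' }
#' @export
run_mc_study <- function(scenarios = c("NN", "TT", "NLap", "contaminated"),
                         q = c(0.5, 0.75, 0.9), R = 500, seed = 1L,
                         estimators = c("MQRE", "MQ", "LRE"), c = 1.345) {
  if (R < 1) stop("R must be at least 1", call. = FALSE)
  # with a single replicate the dispersion summaries are undefined (NA)
  estimators <- match.arg(estimators, several.ok = TRUE)
  scenarios <- match.arg(scenarios,
                         c("NN", "TT", "NLap", "contaminated"),
                         several.ok = TRUE)
  local_seed(seed)
  scn_seeds <- sample.int(2^31 - 2, length(scenarios))
  rep_seed_base <- sample.int(2^31 - 2, length(scenarios))
  ctrl_fast <- mqre_control(ranef = FALSE, cov = TRUE)
  out <- list()

  for (si in seq_along(scenarios)) {
    scn <- mc_scenario(scenarios[si], seed = scn_seeds[si])
    local_seed(rep_seed_base[si])
    rep_seeds <- sample.int(2^31 - 2, R)
    # storage: [rep, coef] per estimator/q
    est <- list(); ses <- list()
    keys <- character()
    for (qq in q) {
      if ("MQRE" %in% estimators) keys <- c(keys, paste0("MQRE.", qq))
      if ("MQ" %in% estimators) keys <- c(keys, paste0("MQ.", qq))
    }
    if ("LRE" %in% estimators && 0.5 %in% q) keys <- c(keys, "LRE.0.5")
    for (k in keys) { est[[k]] <- matrix(NA_real_, R, 2)
                      ses[[k]] <- matrix(NA_real_, R, 2) }

    for (r in seq_len(R)) {
      dat <- mc_draw(scn, rep_seeds[r])
      for (qq in q) {
        if ("MQRE" %in% estimators) {
          f <- tryCatch(suppressWarnings(
            fit_mqre(dat, mq_spec(qq, c), ctrl_fast)),
            error = function(e) NULL)
          if (!is.null(f) && f$converged) {
            est[[paste0("MQRE.", qq)]][r, ] <- f$coefficients
            if (!is.null(f$vcov))
              ses[[paste0("MQRE.", qq)]][r, ] <- sqrt(diag(f$vcov))
          }
        }
        if ("MQ" %in% estimators) {
          f <- tryCatch(fit_mq(dat$X, dat$y, mq_spec(qq, c)),
                        error = function(e) NULL)
          if (!is.null(f) && f$converged)
            est[[paste0("MQ.", qq)]][r, ] <- f$coefficients
        }
      }
      if ("LRE" %in% estimators && 0.5 %in% q) {
        f <- tryCatch(suppressWarnings(
          fit_mqre(dat, mq_spec(0.5, c, loss = "squared"), ctrl_fast)),
          error = function(e) NULL)
        if (!is.null(f) && f$converged) {
          est[["LRE.0.5"]][r, ] <- f$coefficients
          if (!is.null(f$vcov)) ses[["LRE.0.5"]][r, ] <- sqrt(diag(f$vcov))
        }
      }
    }

    terms <- c("intercept", "slope")
    for (k in keys) {
      parts <- strsplit(k, ".", fixed = TRUE)[[1]]
      estname <- parts[1]
      qq <- as.numeric(paste(parts[-1], collapse = "."))
      E <- est[[k]]; S <- ses[[k]]
      ok <- stats::complete.cases(E)
      truth <- mc_truth(scn, qq)
      refk <- paste0("MQ.", qq)
      for (ci in 1:2) {
        e_ok <- E[ok, ci]
        eff_val <- NA_real_
        if (refk %in% names(est) && sum(ok) >= 2) {
          okr <- ok & stats::complete.cases(est[[refk]])
          if (sum(okr) >= 2)
            eff_val <- eff(E[okr, ci], est[[refk]][okr, ci])
        }
        out[[length(out) + 1L]] <- data.frame(
          scenario = scn$id, q = qq, estimator = estname,
          term = terms[ci],
          mean = mean(e_ok),
          emp_se = if (length(e_ok) < 2) NA_real_ else
            sqrt(mean((e_ok - mean(e_ok))^2)),
          est_se = if (all(is.na(S[ok, ci]))) NA_real_ else
            mean(S[ok, ci], na.rm = TRUE),
          arb = arb(e_ok, truth[ci]),
          eff = eff_val,
          reps_used = sum(ok), n_fail = R - sum(ok)
        )
      }
    }
  }
  report <- do.call(rbind, out)
  rownames(report) <- NULL
  attr(report, "R") <- R
  attr(report, "seed") <- seed
  attr(report, "c") <- c
  class(report) <- c("mc_report", "data.frame")
  report
}

#' @export
print.mc_report <- function(x, digits = 4, ...) {
  cat(sprintf("Monte Carlo study report: R = %d, master seed = %d, c = %g\n",
              attr(x, "R"), attr(x, "seed"), attr(x, "c")))
  print.data.frame(x, digits = digits, row.names = FALSE)
  invisible(x)
}

# deterministic RNG entry point for functions that accept a seed
local_seed <- function(seed) {
  seed <- as.integer(seed %% (2^31 - 1))
  set.seed(seed)
  invisible(seed)
}
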