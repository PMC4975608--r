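test_that("squared loss at q = 0.5 reproduces Gaussian ML (lme4 oracle)", {
  skip_if_not_installed("lme4")
  dat <- nn_replicate(design_seed = 42, rep_seed = 1)
  f <- fit_mqre(dat, mq_spec(0.5, loss = "squared"))
  expect_true(f$converged)
  df <- data.frame(y = dat$y, x = dat$X[, 2], g = dat$group)
  m <- lme4::lmer(y ~ x + (1 | g), data = df, REML = FALSE)
  expect_equal(unname(coef(f)), unname(lme4::fixef(m)), tolerance = 1e-3)
  expect_equal(unname(f$varcomp[["sigma2_gamma"]]),
               unname(unlist(lme4::VarCorr(m))[1]), tolerance = 1e-3)
  expect_equal(f$varcomp[["sigma2_eps"]], stats::sigma(m)^2,
               tolerance = 1e-3)
  # predicted random effects match the BLUPs
  expect_equal(unname(f$ranef),
               lme4::ranef(m)[[1]][, 1], tolerance = 1e-3)
})

test_that("beta_step lands on the GLS solution in one step under squared loss", {
  set.seed(10)
  sizes <- c(4, 3, 3)
  g <- rep(1:3, sizes)
  x <- runif(10, 0, 5)
  X <- cbind(1, x)
  y <- 1 + 2 * x + rnorm(3)[g] + rnorm(10)
  dat <- grouped_data(y, X, g)
  sg <- 1.7; se <- 0.9
  Z <- outer(g, 1:3, "==") * 1
  V <- se * diag(10) + sg * Z %*% t(Z)
  gls <- drop(solve(t(X) %*% solve(V, X), t(X) %*% solve(V, y)))
  sp <- mq_spec(0.5, loss = "squared")
  stp <- mqre:::beta_step(dat, c(0, 0), sg, se, sp, s = 1)
  expect_equal(unname(stp$beta), unname(gls), tolerance = 1e-9)
  # at the solution the score is zero and another step does not move
  stp2 <- mqre:::beta_step(dat, gls, sg, se, sp, s = 1)
  expect_equal(unname(stp2$beta), unname(gls), tolerance = 1e-9)
  expect_lt(max(abs(stp2$state$score)), 1e-9)
})

test_that("variance_step is stationary at the fitted variance components", {
  dat <- make_toy_grouped(seed = 12, d = 40, nj = 6, sg = 3, se = 2)
  f <- fit_mqre(dat, mq_spec(0.75))
  expect_true(f$converged)
  sg <- f$varcomp[["sigma2_gamma"]]; se <- f$varcomp[["sigma2_eps"]]
  r <- scaled_residuals(dat, coef(f), sg, se)
  vs <- mqre:::variance_step(dat, r, sg, se, f$spec, f$offset,
                             mqre:::k2_symmetric(f$spec$c, f$spec$loss))
  expect_equal(vs$sigma2_gamma, sg, tolerance = 2e-3)
  expect_equal(vs$sigma2_eps, se, tolerance = 2e-3)
})

test_that("estimating-equation norms are small at convergence", {
  dat <- nn_replicate(design_seed = 42, rep_seed = 5)
  for (sp in list(mq_spec(0.5), mq_spec(0.9),
                  mq_spec(0.75, loss = "squared"))) {
    f <- fit_mqre(dat, sp, mqre_control(ranef = FALSE, cov = FALSE))
    expect_true(f$converged)
    expect_lt(max(f$eq_norms), 1e-6 * dat$n)
  }
})

test_that("with the level-2 variance fixed at zero the fit reduces to fit_mq", {
  dat <- make_toy_grouped(seed = 13, d = 20, nj = 5, sg = 0.5, se = 2)
  sp <- mq_spec(0.75)
  f_red <- fit_mqre(dat, sp,
                    mqre_control(fix_varcomp = c(0, 2), ranef = FALSE))
  f_mq <- fit_mq(dat$X, dat$y, sp)
  expect_equal(unname(coef(f_red)), unname(coef(f_mq)), tolerance = 1e-6)
})

test_that("the fit is scale equivariant (y -> k y)", {
  dat <- make_toy_grouped(seed = 14, d = 30, nj = 7)
  k <- 3
  dat_k <- grouped_data(k * dat$y, dat$X, dat$group)
  for (sp in list(mq_spec(0.5), mq_spec(0.75))) {
    f1 <- fit_mqre(dat, sp, mqre_control(ranef = FALSE, cov = FALSE))
    f2 <- fit_mqre(dat_k, sp, mqre_control(ranef = FALSE, cov = FALSE))
    expect_equal(unname(coef(f2)), unname(k * coef(f1)), tolerance = 1e-3)
    expect_equal(unname(f2$varcomp), unname(k^2 * f1$varcomp),
                 tolerance = 1e-3)
  }
})

test_that("variance components are recovered under the Gaussian core", {
  # moderate replication of the two-level normal model at q = 0.5 and in
  # the tail; the recentred calibration keeps both components consistent
  reps <- 30
  sg_hat <- se_hat <- sg_hat9 <- se_hat9 <- numeric(reps)
  scn <- mc_scenario("NN", seed = 7)
  set.seed(77)
  seeds <- sample.int(1e6, reps)
  for (i in seq_len(reps)) {
    dat <- mc_draw(scn, seeds[i])
    f5 <- fit_mqre(dat, mq_spec(0.5), mqre_control(ranef = FALSE, cov = FALSE))
    f9 <- fit_mqre(dat, mq_spec(0.9), mqre_control(ranef = FALSE, cov = FALSE))
    sg_hat[i] <- f5$varcomp[1]; se_hat[i] <- f5$varcomp[2]
    sg_hat9[i] <- f9$varcomp[1]; se_hat9[i] <- f9$varcomp[2]
  }
  expect_equal(mean(sg_hat), 3, tolerance = 0.12)
  expect_equal(mean(se_hat), 5, tolerance = 0.08)
  expect_equal(mean(sg_hat9), 3, tolerance = 0.15)
  expect_equal(mean(se_hat9), 5, tolerance = 0.12)
})

test_that("expectile random-effects fit matches the scalar expectile oracle", {
  # location-shift normal data, intercept-only fixed part
  set.seed(21)
  d <- 120; nj <- 9
  g <- rep(1:d, each = nj)
  sg <- 3; se <- 5
  y <- 100 + rnorm(d, 0, sqrt(sg))[g] + rnorm(d * nj, 0, sqrt(se))
  dat <- grouped_data(y, matrix(1, d * nj, 1), g)
  f <- fit_expectile_re(dat, q = 0.75,
                        control = mqre_control(ranef = FALSE, cov = FALSE))
  # scalar 0.75-expectile of N(0,1) by root finding
  e75 <- uniroot(function(m)
    0.75 * (dnorm(m) - m * (1 - pnorm(m))) +
      0.25 * (-dnorm(m) - m * pnorm(m)), c(0, 2), tol = 1e-12)$root
  target <- 100 + sqrt(sg + se) * e75
  expect_equal(unname(coef(f)), target, tolerance = 0.005)
})

test_that("intercepts are monotone in q for both loss families", {
  dat <- make_toy_grouped(seed = 23, d = 40, nj = 8, sg = 2, se = 3)
  qs <- c(0.1, 0.25, 0.5, 0.75, 0.9)
  for (loss in c("huber", "squared")) {
    ints <- vapply(qs, function(q)
      unname(coef(fit_mqre(dat, mq_spec(q, loss = loss),
                           mqre_control(ranef = FALSE, cov = FALSE)))[1]),
      numeric(1))
    expect_true(all(diff(ints) > -1e-8))
  }
})

test_that("degenerate inputs are rejected", {
  y <- rnorm(10)
  expect_error(fit_mqre(grouped_data(y, cbind(1, rnorm(10)), rep(1, 10))),
               "two groups")
  dat <- make_toy_grouped(seed = 1, d = 4, nj = 2)
  expect_warning(
    fit_mqre(dat, mq_spec(0.5), mqre_control(maxit = 2, ranef = FALSE,
                                             cov = FALSE)),
    "did not converge")
})
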