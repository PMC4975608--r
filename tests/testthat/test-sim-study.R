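test_that("scenario construction is deterministic with the stated design", {
  scn <- mc_scenario("NN", seed = 9)
  expect_equal(scn$n, 1259L)
  expect_equal(scn$d, 100L)
  expect_equal(sum(scn$sizes), 1259L)
  expect_true(all(scn$sizes >= 5 & scn$sizes <= 20))
  expect_true(all(scn$x1 >= 0 & scn$x1 <= 20))
  scn2 <- mc_scenario("NN", seed = 9)
  expect_identical(scn, scn2)
  expect_error(mc_scenario("bogus", 1))
})

test_that("replicate draws have the nominal error moments", {
  scn <- mc_scenario("NN", seed = 9)
  expect_identical(mc_draw(scn, 4)$y, mc_draw(scn, 4)$y)
  # pooled across replicates: total error variance = 3 + 5
  set.seed(1)
  errs <- unlist(lapply(1:40, function(r) {
    d <- mc_draw(scn, 100 + r)
    d$y - 100 - 2 * scn$x1
  }))
  expect_equal(var(errs), 8, tolerance = 0.15)
  # within-group deviations isolate the level-1 error
  scn_l <- mc_scenario("NLap", seed = 9)
  within <- unlist(lapply(1:40, function(r) {
    d <- mc_draw(scn_l, 200 + r)
    res <- d$y - 100 - 2 * scn_l$x1
    res - ave(res, d$group)
  }))
  infl <- mean(1 - 1 / scn_l$sizes[scn_l$group])  # deflation from centring
  expect_equal(var(within) / infl, 5, tolerance = 0.1)
  # heavy level-1 tails: excess kurtosis of the Laplace near 3
  kurt <- mean(within^4) / mean(within^2)^2 - 3
  expect_gt(kurt, 1.5)
  # contamination inflates the level-2 spread of the last ten groups
  scn_c <- mc_scenario("contaminated", seed = 9)
  gm <- sapply(1:30, function(r) {
    d <- mc_draw(scn_c, 300 + r)
    res <- d$y - 100 - 2 * scn_c$x1
    tapply(res, d$group, mean)
  })
  expect_gt(var(as.numeric(gm[91:100, ])), 2 * var(as.numeric(gm[1:90, ])))
})

test_that("true parameters follow the nominal level-1 quantiles", {
  expect_equal(unname(mc_truth("NN", 0.5)), c(100, 2))
  expect_equal(mc_truth("NN", 0.75)[["intercept"]],
               100 + qnorm(0.75) * sqrt(5), tolerance = 1e-12)
  expect_equal(mc_truth("contaminated", 0.9)[["intercept"]],
               100 + qnorm(0.9) * sqrt(5), tolerance = 1e-12)
  expect_equal(mc_truth("TT", 0.9)[["intercept"]], 100 + qt(0.9, 3))
  # Laplace quantile agrees with a numerical inverse of its CDF
  plap <- function(x, b = 1.58)
    ifelse(x < 0, 0.5 * exp(x / b), 1 - 0.5 * exp(-x / b))
  q75 <- uniroot(function(x) plap(x) - 0.75, c(-20, 20), tol = 1e-12)$root
  expect_equal(mc_truth("NLap", 0.75)[["intercept"]], 100 + q75,
               tolerance = 1e-9)
})

test_that("ARB and EFF formulas", {
  expect_equal(arb(c(1, 1, 1), 1), 0)
  expect_equal(arb(c(1.1, 0.9), 1), 0)
  expect_equal(arb(2.02, 2), 1)
  expect_error(arb(1, 0), "theta = 0")
  x <- rnorm(50)
  expect_equal(eff(x, x), 1)
  expect_equal(eff(0.5 * x, x), 0.25)
  expect_error(eff(x, rep(1, 50)), "zero variance")
  expect_error(eff(1, x), "2 replicates")
})

test_that("a two-replicate study equals hand-assembled individual fits", {
  master <- 314
  rep_small <- run_mc_study("NN", q = 0.5, R = 2, seed = master,
                            estimators = c("MQRE", "MQ"))
  # mirror the internal seed derivation
  set.seed(master)
  scn_seed <- sample.int(2^31 - 2, 1)
  rep_base <- sample.int(2^31 - 2, 1)
  scn <- mc_scenario("NN", seed = scn_seed)
  set.seed(rep_base)
  rep_seeds <- sample.int(2^31 - 2, 2)
  b_mqre <- t(sapply(rep_seeds, function(s) {
    coef(fit_mqre(mc_draw(scn, s), mq_spec(0.5, 1.345),
                  mqre_control(ranef = FALSE, cov = FALSE)))
  }))
  b_mq <- t(sapply(rep_seeds, function(s) {
    dat <- mc_draw(scn, s)
    coef(fit_mq(dat$X, dat$y, mq_spec(0.5, 1.345)))
  }))
  got <- rep_small[rep_small$estimator == "MQRE" &
                     rep_small$term == "slope", ]
  expect_equal(got$mean, mean(b_mqre[, 2]), tolerance = 1e-10)
  expect_equal(got$eff, eff(b_mqre[, 2], b_mq[, 2]), tolerance = 1e-10)
  expect_equal(got$reps_used, 2)
  # reference efficiency of MQ against itself is exactly 1
  expect_true(all(rep_small$eff[rep_small$estimator == "MQ"] == 1))
})

test_that("study reports are reproducible and flag undefined dispersion", {
  r1 <- run_mc_study("NN", q = 0.5, R = 3, seed = 5, estimators = "MQ")
  r2 <- run_mc_study("NN", q = 0.5, R = 3, seed = 5, estimators = "MQ")
  expect_identical(as.data.frame(r1), as.data.frame(r2))
  r_one <- run_mc_study("NN", q = 0.5, R = 1, seed = 5, estimators = "MQ")
  expect_true(all(is.na(r_one$emp_se)))
  expect_true(all(is.na(r_one$eff)))
})
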