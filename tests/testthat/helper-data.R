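# small two-level Gaussian datasets built in code for unit tests
make_toy_grouped <- function(seed = 1, d = 25, nj = 8,
                             sg = 2, se = 1, beta = c(3, 1.5)) {
  set.seed(seed)
  sizes <- if (length(nj) == 1) rep(nj, d) else nj
  g <- rep(seq_len(d), sizes)
  n <- length(g)
  x <- runif(n, 0, 10)
  y <- beta[1] + beta[2] * x + rnorm(d, 0, sqrt(sg))[g] + rnorm(n, 0, sqrt(se))
  grouped_data(y, cbind(`(Intercept)` = 1, x = x), g)
}

# one replicate of the normal/normal study design (full scale n = 1259)
nn_replicate <- function(design_seed = 42, rep_seed = 1) {
  scn <- mc_scenario("NN", seed = design_seed)
  mc_draw(scn, rep_seed)
}
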