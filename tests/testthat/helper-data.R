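# shared fixtures, built in code

# Pearson chi-square of a 2x2 table by the hand formula n(ad - bc)^2 / (row/col products)
pearson_2x2 <- function(a, b, c, d) {
  n <- a + b + c + d
  n * (a * d - b * c)^2 / ((a + b) * (c + d) * (a + c) * (b + d))
}

# small logistic dataset with one adjustment covariate; null unless delta != 0
make_logit_data <- function(n, seed, delta = 0, tau = 0.5, prevalence = 0.3) {
  ef <- if (delta == 0) no_effect() else threshold_effect(tau, delta)
  generate_scenario(scenario_spec(n = n, family = "binomial",
                                  z_dists = "normal", gamma_z = 0.3,
                                  target_mean = prevalence, effect = ef,
                                  seed = seed))
}

fl_logit <- family_link("binomial", "logit")
fl_gauss <- family_link("gaussian", "identity")
fl_pois  <- family_link("poisson", "log")
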