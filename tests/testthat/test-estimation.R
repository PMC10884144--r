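test_that("variant configurations match the model list", {
  fixed <- c(FALSE, TRUE, FALSE, TRUE, FALSE, TRUE)
  iiv_m <- c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE)
  iiv_t <- c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE)
  for (v in 1:6) {
    cfg <- variant_config(v)
    expect_equal(cfg$ada_modes_fixed, fixed[v])
    expect_equal(cfg$iiv_on_modes, iiv_m[v])
    expect_equal(cfg$iiv_on_transitions, iiv_t[v])
  }
  expect_error(variant_config(7), "1..6")
})

test_that("pack/unpack round-trips free parameters to 1e-12", {
  set.seed(31)
  for (v in 1:6) {
    for (obs in c("both", "pk", "ada")) {
      cfg <- variant_config(v)
      if (obs != "both") cfg <- decouple_univariate(cfg, obs)
      em <- emission_params(
        mu_pkres_noada = rnorm(1), mu_pkres_ada = rnorm(1),
        mu_ada_noada = runif(1, 0.2, 1), mu_ada_ada = runif(1, 2, 4),
        sigma2_pkres = runif(1, 0.3, 2), sigma2_ada = runif(1, 0.3, 3),
        rho_noada = runif(1, -0.8, 0.8), rho_ada = runif(1, -0.8, 0.8),
        omega2_mu_pkres = runif(1, 0.01, 0.5),
        omega2_mu_ada = runif(1, 0.01, 0.5))
      tp <- transition_params_from_probs(runif(1, 0.01, 0.4),
                                         runif(1, 0.001, 0.2),
                                         omega2_pi12 = runif(1, 0.01, 0.5),
                                         omega2_pi21 = runif(1, 0.01, 0.5))
      u <- pack_params(em, tp, cfg)
      back <- unpack_params(u, cfg, list(em = em, tp = tp))
      u2 <- pack_params(back$em, back$tp, cfg)
      expect_equal(u, u2, tolerance = 1e-12)
    }
  }
  # simple fixed points of the transforms
  cfg6 <- variant_config(6)
  init <- default_init(cfg6)
  u <- pack_params(init$em, init$tp, cfg6)
  expect_equal(unname(u["sigma2_pkres"]), 0)     # log(1)
  expect_equal(unname(u["rho_noada"]), 0)        # atanh(0)
})

test_that("population likelihood chains to the per-subject forward recursion", {
  em <- table3_em()
  tp <- table3_tp()
  cfg <- variant_config(6)
  one <- data.frame(subject_id = "A", time = 14, y_pkres = -0.5, y_ada = 2.9)
  expect_equal(population_loglik(one, em, tp, cfg),
               emission_logpdf(-0.5, 2.9, "S_NOADA", em))

  sim <- simulate_mhmm(25, 6, em, tp, seed = 3)
  by_subject <- vapply(split(sim$records, sim$records$subject_id),
                       function(r) forward_loglik(r, em, tp)$loglik, 0)
  expect_equal(population_loglik(sim$records, em, tp, cfg),
               sum(by_subject), tolerance = 1e-10)

  # likelihood is invariant to row shuffles that preserve records
  set.seed(8)
  shuffled <- sim$records[sample(nrow(sim$records)), ]
  expect_equal(population_loglik(shuffled, em, tp, cfg),
               population_loglik(sim$records, em, tp, cfg))
})

test_that("zero random-effect variance reduces to the no-IIV likelihood", {
  em <- table3_em()
  tp <- table3_tp()  # omega2 fields are 0
  sim <- simulate_mhmm(15, 8, em, tp, seed = 21)
  ll4 <- population_loglik(sim$records, em, tp, variant_config(4))
  ll6 <- population_loglik(sim$records, em, tp, variant_config(6))
  expect_identical(ll4, ll6)
})

test_that("quadrature matches dense-grid integration on a 1-D IIV toy", {
  em <- table3_em()
  omega2 <- 0.25
  tp <- transition_params_from_probs(0.2, 0.05, omega2_pi12 = omega2)
  r <- data.frame(subject_id = "A", time = c(14, 28, 42),
                  y_pkres = c(0.2, -1.4, -1.8), y_ada = c(0.5, 2.7, 3.1))
  # brute-force trapezoid over eta on [-8 sd, 8 sd]
  sdv <- sqrt(omega2)
  eta <- seq(-8 * sdv, 8 * sdv, length.out = 1e5)
  vals <- vapply(eta, function(e) {
    exp(forward_loglik(r, em, tp, etas = list(pi12 = e))$loglik) *
      dnorm(e, 0, sdv)
  }, 0)
  oracle <- log(sum((vals[-1] + vals[-length(vals)]) / 2 * diff(eta)))
  expect_equal(population_loglik(r, em, tp, variant_config(4), nodes = 40),
               oracle, tolerance = 1e-6)
  # node-count stability at the default working resolution
  ll9 <- population_loglik(r, em, tp, variant_config(4), nodes = 9)
  ll15 <- population_loglik(r, em, tp, variant_config(4), nodes = 15)
  expect_lt(abs(ll9 - ll15), 1e-4)
})

test_that("the fitted optimum dominates the generating parameters", {
  gp <- czp_example_params()
  sim <- simulate_mhmm(200, 8, gp$em, gp$tp, seed = 14)
  fit <- fit_mhmm(sim$records, variant_config(6), seed = 2)
  expect_true(fit$converged)
  expect_gte(fit$loglik,
             population_loglik(sim$records, gp$em, gp$tp, variant_config(6)))
})

test_that("a no-transition dataset pushes pi12 to the boundary and is flagged", {
  # emission distributions known (fixed at generating values) and pi21 fixed:
  # with no simulated transitions the MLE of pi12 collapses to the boundary
  gp <- czp_example_params()
  tp0 <- transition_params(-1e10, stats::qlogis(0.1))
  sim <- simulate_mhmm(150, 8, gp$em, tp0, seed = 17)
  init <- list(em = gp$em, tp = table3_tp())
  fit <- fit_mhmm(sim$records, variant_config(6), init = init, seed = 1,
                  fixed = c("mu_pkres_noada", "mu_pkres_ada", "sigma2_pkres",
                            "sigma2_ada", "rho_noada", "rho_ada", "pi21"))
  expect_lt(fit$estimates[["pi12"]], 1 / nrow(sim$records))
  expect_true(fit$boundary[["pi12"]])
})

test_that("decoupled univariate models drop the other variable's parameters", {
  cfg_pk <- decouple_univariate(variant_config(6), "pk")
  nm <- names(pack_params(table3_em(), table3_tp(), cfg_pk))
  expect_setequal(nm, c("mu_pkres_noada", "mu_pkres_ada", "sigma2_pkres",
                        "pi12", "pi21"))
  cfg_ada <- decouple_univariate(variant_config(5), "ada")
  nm2 <- names(pack_params(table3_em(), table3_tp(), cfg_ada))
  expect_setequal(nm2, c("mu_ada_noada", "mu_ada_ada", "sigma2_ada",
                         "pi12", "pi21"))
})

test_that("with rho = 0 the likelihood factorizes where the path is determined", {
  # The emission density factorizes at rho = 0, so the bivariate likelihood
  # equals the product of the univariate ones exactly when a single state
  # path carries the probability mass; with a genuinely uncertain path the
  # marginal likelihood mixes over paths and the identity cannot hold.
  em <- emission_params(mu_pkres_noada = 0.3, mu_pkres_ada = -1.6,
                        sigma2_pkres = 0.8, sigma2_ada = 1.6)
  cfg <- variant_config(6)
  cfg_pk <- decouple_univariate(cfg, "pk")
  cfg_ada <- decouple_univariate(cfg, "ada")

  # single-record series: likelihood is the S_NOADA emission
  tp <- table3_tp()
  sim1 <- simulate_mhmm(60, 1, em, tp, seed = 23)
  expect_equal(population_loglik(sim1$records, em, tp, cfg),
               population_loglik(sim1$records, em, tp, cfg_pk) +
                 population_loglik(sim1$records, em, tp, cfg_ada),
               tolerance = 1e-9)

  # degenerate chain (pi12 numerically 0): all mass on the all-S_NOADA path
  tp0 <- transition_params(-1e10, stats::qlogis(0.1))
  sim2 <- simulate_mhmm(40, 10, em, tp0, seed = 24)
  expect_equal(population_loglik(sim2$records, em, tp0, cfg),
               population_loglik(sim2$records, em, tp0, cfg_pk) +
                 population_loglik(sim2$records, em, tp0, cfg_ada),
               tolerance = 1e-9)

  # with an uncertain path the bivariate likelihood exceeds the factorized
  # sum on data generated from the model (both variables favour the true path)
  sim3 <- simulate_mhmm(40, 10, em, tp, seed = 25)
  expect_gt(population_loglik(sim3$records, em, tp, cfg),
            population_loglik(sim3$records, em, tp, cfg_pk) +
              population_loglik(sim3$records, em, tp, cfg_ada))
})

test_that("an ADA-only series with no signal decodes to all S_NOADA", {
  em <- table3_em()
  r <- data.frame(y_pkres = rep(NA_real_, 6),
                  y_ada = rep(0.6, 6), time = 14 * 1:6)
  v <- viterbi_decode(r, em, table3_tp())
  expect_true(all(v$states == "S_NOADA"))
})

test_that("standard errors: delta method, fixed parameters absent, 1/sqrt(n) scaling", {
  gp <- czp_example_params()
  sim1 <- simulate_mhmm(300, 8, gp$em, gp$tp, seed = 5)
  fit1 <- fit_mhmm(sim1$records, variant_config(6), seed = 1, se = TRUE)
  tab1 <- fit1$se_table
  expect_true(attr(tab1, "cov_ok"))
  # fixed ADA modes are not estimated and carry no SE entry
  expect_false(any(c("mu_ada_noada", "mu_ada_ada") %in% tab1$parameter))
  est <- tab1[tab1$parameter == "mu_pkres_noada", ]
  expect_equal(est$rse_percent, 100 * est$se / abs(est$estimate))
  expect_true(all(tab1$se[is.finite(tab1$se)] >= 0))

  sim2 <- simulate_mhmm(1200, 8, gp$em, gp$tp, seed = 5)
  fit2 <- fit_mhmm(sim2$records, variant_config(6), seed = 1, se = TRUE)
  tab2 <- fit2$se_table
  for (p in c("mu_pkres_noada", "sigma2_pkres", "pi12")) {
    r1 <- tab1$se[tab1$parameter == p]
    r2 <- tab2$se[tab2$parameter == p]
    # quadrupling the cohort should roughly halve the SE
    expect_lt(r2, r1)
    expect_lt(r2 / r1, 0.75)
  }
})

test_that("replicate fits recover the generating values within Monte-Carlo error", {
  gp <- czp_example_params()
  keep <- c("mu_pkres_noada", "mu_pkres_ada", "sigma2_pkres", "sigma2_ada",
            "pi12")
  truth <- c(0.3, -1.6, 0.8, 1.6, 0.03)
  ests <- t(vapply(1:20, function(k) {
    sim <- simulate_mhmm(200, 8, gp$em, gp$tp, seed = 1000 + k)
    fit_mhmm(sim$records, variant_config(6), seed = k)$estimates[keep]
  }, setNames(numeric(5), keep)))
  mc_se <- apply(ests, 2, sd) / sqrt(nrow(ests))
  expect_true(all(abs(colMeans(ests) - truth) < 3 * mc_se),
              info = paste(round(colMeans(ests), 4), collapse = ", "))
})

test_that("fit results serialize to JSON and back", {
  gp <- czp_example_params()
  sim <- simulate_mhmm(80, 8, gp$em, gp$tp, seed = 2)
  fit <- fit_mhmm(sim$records, variant_config(6), seed = 1)
  path <- tempfile(fileext = ".json")
  write_fit_json(fit, path)
  back <- read_fit_json(path)
  expect_equal(back$em$mu_pkres_ada, fit$em$mu_pkres_ada)
  expect_equal(plogis(back$tp$logit_pi12), fit$estimates[["pi12"]])
  expect_equal(back$loglik, fit$loglik)
  tab <- fit_parameter_table(fit)
  expect_setequal(tab$parameter, names(fit$estimates))
})
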