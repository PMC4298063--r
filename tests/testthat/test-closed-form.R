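test_that("appropriate-method estimands equal the true effect exactly, for any parameters", {
  for (loading in c(0.1, 0.4, 0.6)) {
    for (stability in c(0.1, 0.5, 0.7)) {
      for (b_pred in c(-0.1, 0.1, 0.2)) {
        tr <- population_spec("transient", "mar", loading = loading,
                              stability = stability, b_pred = b_pred)
        en <- population_spec("enduring", "mar", loading = loading,
                              stability = stability, b_pred = b_pred)
        expect_equal(mr_estimand(tr), b_pred, tolerance = 1e-12)
        expect_equal(cs_estimand(en), b_pred, tolerance = 1e-12)
        # MR also recovers the stability path in the transient population
        expect_equal(unname(mr_coefficients(tr)[["h1"]]), stability,
                     tolerance = 1e-12)
      }
    }
  }
})

test_that("inappropriate estimands match hand-derived moment algebra", {
  # enduring MR: partial coefficient from sigma_P,H2 = .26,
  # sigma_H1,H2 = .596, sigma_P,H1 = .16
  expect_equal(mr_estimand(population_spec("enduring")),
               (0.26 - 0.596 * 0.16) / (1 - 0.16^2), tolerance = 1e-12)
  # transient change score: b_pred - stability * loading^2
  expect_equal(cs_estimand(population_spec("transient")),
               0.1 - 0.5 * 0.16, tolerance = 1e-12)
  # independent variables carry no association
  id4 <- diag(4)
  dimnames(id4) <- list(STUDY_VARS, STUDY_VARS)
  expect_equal(mr_estimand(id4), 0, tolerance = 1e-12)
  expect_equal(cs_estimand(id4), 0, tolerance = 1e-12)
})

test_that("selection moments obey the truncated-normal identities", {
  spec <- population_spec("transient", "mnar-strong")
  sm <- selection_moments(spec, 0.5)
  # half-normal: mean -sqrt(2/pi), variance 1 - 2/pi
  expect_equal(unname(sm$mean[["liability"]]), -sqrt(2 / pi),
               tolerance = 1e-12)
  expect_equal(sm$cov["liability", "liability"], 1 - 2 / pi,
               tolerance = 1e-12)
  expect_equal(sm$threshold, stats::qnorm(0.5), tolerance = 1e-12)
  expect_equal(sm$retained_fraction, 0.5)
  # truncation strictly shrinks the liability direction
  expect_lt(sm$cov["liability", "liability"], 1)
  expect_gte(min(eigen(sm$cov, symmetric = TRUE)$values), -1e-10)

  # no attrition: moments unchanged
  sm0 <- selection_moments(spec, 0)
  expect_equal(unname(sm0$mean), rep(0, 4))
  expect_equal(sm0$cov, unclass(implied_covariance(spec)), tolerance = 1e-15)

  # MCAR: liability independent of study variables, their moments unchanged
  mcar <- selection_moments(population_spec("transient", "mcar"), 0.5)
  vars <- c("predictor", "h1", "h2")
  expect_equal(unname(mcar$mean[vars]), rep(0, 3), tolerance = 1e-12)
  expect_equal(mcar$cov[vars, vars],
               unclass(implied_covariance(population_spec("transient")))[vars, vars],
               tolerance = 1e-12)

  expect_error(selection_moments(spec, 1), "rate")
  expect_error(selection_moments(spec, -0.1), "rate")
})

test_that("attrition estimands compose selection with the regression estimands", {
  for (cause in c("transient", "enduring")) {
    spec <- population_spec(cause, "mnar-weak")
    expect_equal(attrition_estimand(spec, "mr", 0), mr_estimand(spec),
                 tolerance = 1e-12)
    expect_equal(attrition_estimand(spec, "change_score", 0),
                 cs_estimand(spec), tolerance = 1e-12)
  }
  # sign antisymmetry of every estimand
  for (scen in canonical_scenarios) {
    for (method in c("mr", "change_score")) {
      for (rate in c(0, 0.3, 0.5, 0.7)) {
        pos <- attrition_estimand(population_spec("transient", scen, "positive"),
                                  method, rate)
        neg <- attrition_estimand(population_spec("transient", scen, "negative"),
                                  method, rate)
        expect_equal(neg, -pos, tolerance = 1e-12)
      }
    }
  }
})

test_that("closed-form estimands agree with huge-n empirical rank-deletion", {
  n <- 3e5
  cases <- list(
    list(spec = population_spec("transient", "mnar-strong"), method = "mr"),
    list(spec = population_spec("enduring", "mar"), method = "change_score"),
    list(spec = population_spec("enduring", "mnar-strong"), method = "mr")
  )
  for (case in cases) {
    for (rate in c(0.3, 0.5, 0.7)) {
      fit <- empirical_truncation_fit(case$spec, rate, case$method, n,
                                      seed = 2024)
      expect_lt(
        abs(fit$b_pred_hat - attrition_estimand(case$spec, case$method, rate)),
        3 * fit$se,
        label = sprintf("|%s/%s rate %.1f deviation|", case$spec$cause_type,
                        case$method, rate)
      )
    }
  }
  # mean change-score displacement oracle
  spec <- population_spec("enduring", "mar")
  fit <- empirical_truncation_fit(spec, 0.5, "change_score", n, seed = 77)
  expect_lt(abs(fit$mean_diff - diff_estimand(spec, 0.5)),
            3 * sqrt(2 / fit$n_used))
})

test_that("estimand grid flags the unbiased cells", {
  grid <- estimand_grid(rates = c(0, 0.5))
  expect_equal(nrow(grid), 2 * 4 * 2 * 2)
  unbiased <- grid$appropriate & grid$rate == 0
  expect_equal(grid$estimand[unbiased], grid$true_effect[unbiased],
               tolerance = 1e-12)
  expect_true(all(is.na(grid$diff[grid$method == "mr"])))
  expect_equal(grid$diff[grid$method == "change_score" & grid$rate == 0],
               rep(0, sum(grid$method == "change_score" & grid$rate == 0)),
               tolerance = 1e-12)
})
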