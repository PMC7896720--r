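# one moderately sized fit shared across blocks; small chains are enough
# for the structural checks here (the full-size recovery study lives in
# the acceptance tests)
quick_fit <- local({
  memo <- NULL
  function() {
    if (is.null(memo)) {
      gs <- simulate_growth(growth_sim_config(n_per_cell = 40, seed = 501))
      memo <<- list(
        sim = gs,
        fit = suppressWarnings(fit_growth(
          gs$data, mcmc_config(n_iter = 4000, n_warmup = 1000, thin = 1,
                               chains = 2, seed = 501)))
      )
    }
    memo
  }
})

test_that("the fit recovers generator parameters to posterior precision", {
  # single-seed smoke check: every key parameter within 4 posterior sds of
  # truth (the calibrated 95%-CI coverage study is an acceptance property)
  qf <- quick_fit()
  td <- tidy(qf$fit)
  tr <- qf$sim$truth
  for (term in c("beta1", "beta4", "beta5", "mu_beta2", "sigma")) {
    row <- td[td$term == term, ]
    true <- switch(term, beta1 = tr$beta1, beta4 = tr$beta4,
                   beta5 = tr$beta5, mu_beta2 = tr$mu_beta2, sigma = tr$sigma)
    expect_lt(abs(row$estimate - true) / row$std.error, 4)
  }
})

test_that("fits are bit-reproducible under a fixed seed", {
  gs <- simulate_growth(growth_sim_config(n_per_cell = 10, seed = 7))
  cfg <- mcmc_config(n_iter = 800, n_warmup = 300, thin = 1, chains = 2, seed = 7)
  f1 <- suppressWarnings(fit_growth(gs$data, cfg))
  f2 <- suppressWarnings(fit_growth(gs$data, cfg))
  expect_identical(f1$draws, f2$draws)
  expect_identical(f1$summary, f2$summary)
})

test_that("derived quantities are deterministic functions of saved draws", {
  qf <- quick_fit()
  p1 <- predict_age11(qf$fit, "south", "contemporary")
  p2 <- predict_age11(qf$fit, "south", "contemporary")
  expect_identical(p1$value, p2$value)
  expect_identical(tidy(p1), tidy(p2))
  # the contrast equals -beta5 draw for draw: river terms cancel
  ct <- contrast_south_minus_north(qf$fit)
  expect_equal(ct$value, -qf$fit$draws$beta5, tolerance = 1e-12)
  # and declines decompose the contrast
  ds <- period_decline(qf$fit, "south")
  dn <- period_decline(qf$fit, "north")
  expect_equal(ct$value, ds$value - dn$value, tolerance = 1e-12)
})

test_that("predictions reduce to arithmetic on degenerate draws", {
  qf <- quick_fit()
  fit <- qf$fit
  # overwrite the draws with a single all-zero parameter draw except
  # beta0 = 200, beta1 = 25: an age-11 prediction must be exactly 475
  d <- fit$draws[1, ]
  d[setdiff(names(d), c("chain", "iter"))] <- 0
  rn <- fit$rivers$river
  for (j in rn) {
    d[[paste0("uv1_", j)]] <- 200 + 25 * fit$mean_age  # centered intercept
    d[[paste0("uv2_", j)]] <- 25
  }
  fit2 <- fit
  fit2$draws <- d
  p <- predict_age11(fit2, "north", "historical", age = 11, sex_mix = 0.5)
  expect_equal(p$value, 475)
  expect_equal(predict_age11(fit2, "south", "contemporary")$value, 475)
})

test_that("sex mix and age enter predictions as configured", {
  qf <- quick_fit()
  p_f <- predict_age11(qf$fit, "north", "historical", sex_mix = 0)
  p_m <- predict_age11(qf$fit, "north", "historical", sex_mix = 1)
  expect_equal(p_m$value - p_f$value, qf$fit$draws$mu_beta2, tolerance = 1e-12)
})

test_that("degenerate designs and unrepresented cells raise errors", {
  gs <- simulate_growth(growth_sim_config(n_per_cell = 5, seed = 3))
  d <- gs$data
  expect_error(fit_growth(d[d$location == "south", ], mcmc_config()),
               "north")
  expect_error(fit_growth(d[d$history == "historical", ], mcmc_config()),
               "contemporary")
  one_river <- d[d$river == "Takwa", ]
  expect_error(fit_growth(one_river, mcmc_config()), "two rivers")

  # a fit whose data lack the south x contemporary cell cannot answer the
  # contrast: the error names the cell
  qf <- quick_fit()
  fit2 <- qf$fit
  fit2$cells <- fit2$cells[!(fit2$cells$location == "south" &
                               fit2$cells$history == "contemporary"), ]
  expect_error(predict_age11(fit2, "south", "contemporary"),
               "south x contemporary")
  expect_error(contrast_south_minus_north(fit2), "south x contemporary")
})

test_that("tidy and glance expose broom-shaped summaries with diagnostics", {
  qf <- quick_fit()
  td <- tidy(qf$fit)
  expect_true(all(c("term", "estimate", "std.error", "conf.low", "conf.high",
                    "rhat", "ess") %in% names(td)))
  expect_true(all(c("beta0", "beta1", "beta3", "beta4", "beta5", "sigma",
                    "tau0", "tau1", "rho") %in% td$term))
  expect_true(all(td$conf.low <= td$conf.high))
  gl <- glance(qf$fit)
  expect_equal(gl$nobs, nrow(qf$sim$data))
  expect_equal(gl$n_rivers, 4)
  tc <- tidy(contrast_south_minus_north(qf$fit))
  expect_true(all(c("estimate", "conf.low", "conf.high", "prob_below_zero")
                  %in% names(tc)))
})

test_that("null simulations centre the contrast on zero", {
  gs <- simulate_growth(growth_sim_config(n_per_cell = 40, beta4 = 0, beta5 = 0,
                                          seed = 601))
  fit <- suppressWarnings(fit_growth(
    gs$data, mcmc_config(n_iter = 4000, n_warmup = 1000, thin = 1,
                         chains = 2, seed = 601)))
  tc <- tidy(contrast_south_minus_north(fit))
  expect_lt(abs(tc$estimate) / tc$std.error, 4)
  expect_gt(tc$prob_below_zero, 0.001)
  expect_lt(tc$prob_below_zero, 0.999)
})
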