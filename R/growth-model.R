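#' MCMC configuration for the length-at-age model
#'
#' Defaults follow the analysis this package reproduces: 10,000 total
#' steps per chain of which 5,000 are warmup, retaining every 10th draw.
#' The number of chains is not fixed by that analysis; four are run by
#' default so that split-chain diagnostics are meaningful.
#'
#' @param n_iter Total MCMC steps per chain, warmup included.
#' @param n_warmup Warmup (burn-in) steps per chain.
#' @param thin Keep every `thin`-th post-warmup draw.
#' @param chains Number of chains.
#' @param seed Optional integer seed; per-chain RNG seeds are derived from
#'   it, so a fixed seed makes the fit bit-reproducible.
#' @param adapt JAGS adaptation steps before warmup.
#' @param prior_mean_sd_mult Vague normal priors on mean parameters have
#'   sd `prior_mean_sd_mult * SD(length)` (default 10).
#' @param prior_scale_mult Half-Cauchy priors on scale parameters have
#'   scale `prior_scale_mult * SD(length)` (default 5).
#' @return A list of class `mcmc_config`.
#' @export
mcmc_config <- function(n_iter = 10000, n_warmup = 5000, thin = 10,
                        chains = 4, seed = NULL, adapt = 500,
                        prior_mean_sd_mult = 10, prior_scale_mult = 5) {
  if (n_warmup >= n_iter) abort("`n_warmup` must be smaller than `n_iter`.")
  if (thin < 1) abort("`thin` must be at least 1.")
  if (chains < 1) abort("need at least one chain.")
  structure(
    list(n_iter = n_iter, n_warmup = n_warmup, thin = thin, chains = chains,
         seed = seed, adapt = adapt,
         prior_mean_sd_mult = prior_mean_sd_mult,
         prior_scale_mult = prior_scale_mult),
    class = "mcmc_config"
  )
}

# The likelihood is the hierarchical length-at-age model; four exact
# reparameterizations are applied for Gibbs mixing, none of which changes
# the posterior of any reported quantity:
#   - age is centered (intercepts mapped back afterwards);
#   - river intercept/slope pairs are hierarchically centered around
#     (b0c + b3*south_j, b1);
#   - the bivariate river effect is written as p(u0) p(u1 | u0) with scalar
#     normal nodes, so the glm module can block-update every location
#     parameter jointly;
#   - the history effect is parameterized per location (d_north, d_south),
#     with b4 = d_north and b5 = d_south - d_north derived.
# Half-Cauchy scale priors use dscaled.gamma(scale, df = 1), the half-t
# with 1 degree of freedom; the correlation prior is uniform on [-1, 1],
# i.e. the concentration-1 prior for a 2x2 correlation matrix.
.growth_model_string <- "
model {
  for (i in 1:N) {
    y[i] ~ dnorm(mu[i], prec)
    mu[i] <- uv1[river[i]] + b2[river[i]]*sex[i] +
             uv2[river[i]]*agec[i] + d[loc[i]]*contemp[i]
  }
  for (l in 1:2) { d[l] ~ dnorm(0, pv) }
  b4 <- d[1]
  b5 <- d[2] - d[1]
  for (j in 1:J) {
    uv1[j] ~ dnorm(b0c + b3*southj[j], ptau0)
    uv2[j] ~ dnorm(b1 + slope*(uv1[j] - b0c - b3*southj[j]), pcond)
    b2[j] ~ dnorm(mu_b2, prec_b2)
  }
  slope <- rho*tau1/tau0
  pcond <- 1/(tau1*tau1*(1-rho*rho))
  rho ~ dunif(-1,1)
  ptau0 ~ dscaled.gamma(A, 1); tau0 <- 1/sqrt(ptau0)
  ptau1 ~ dscaled.gamma(A, 1); tau1 <- 1/sqrt(ptau1)
  prec_b2 ~ dscaled.gamma(A, 1); sig_b2 <- 1/sqrt(prec_b2)
  prec ~ dscaled.gamma(A, 1); sigma <- 1/sqrt(prec)
  b0c ~ dnorm(0, pv); b1 ~ dnorm(0, pv); b3 ~ dnorm(0, pv); mu_b2 ~ dnorm(0, pv)
}"

#' Fit the hierarchical Bayesian length-at-age model
#'
#' Fits, by MCMC, the model
#' \deqn{\mathrm{Length} \sim N(\mu, \sigma), \quad
#'   \mu = \beta_0 + u_{0j} + \beta_{2j}\,\mathrm{sex} +
#'   (\beta_1 + u_{1j})\,\mathrm{age} + \beta_3\,\mathrm{south} +
#'   \beta_4\,\mathrm{contemp} + \beta_5\,\mathrm{south\times contemp}}
#' with correlated river-level intercept/slope deviations
#' \eqn{(u_{0j}, u_{1j})} (scales \eqn{\tau_0, \tau_1}, correlation
#' \eqn{\rho}), river-level sex effects \eqn{\beta_{2j} \sim
#' N(\mu_{\beta_2}, \sigma_{\beta_2})}, vague normal priors on mean
#' parameters, half-Cauchy priors on scales, and a uniform prior on the
#' random-effect correlation. Sex is coded 0 = female, 1 = male; age is in
#' years, length in mm.
#'
#' Convergence is summarized per reported quantity by the Gelman-Rubin
#' statistic and effective sample size; failing the conventional bar
#' (R-hat < 1.01, ESS > 1,000) raises a warning, not an error.
#'
#' @param data A growth dataset: tibble with columns `river`, `location`
#'   (`"north"`/`"south"`), `history` (`"historical"`/`"contemporary"`),
#'   `sex` (`"female"`/`"male"`), `age`, `length`.
#' @param config An [mcmc_config()].
#' @param quiet Suppress JAGS progress output (default `TRUE`).
#' @return An object of class `growth_fit`: list with `draws` (tibble, one
#'   row per retained draw, with `chain`, `iter`, fixed effects on the
#'   original age scale, scales, and per-river effects), `summary` (tibble
#'   with posterior mean, sd, 95% credible interval, `rhat`, `ess` per
#'   term), `rivers`, `cells` (design-cell counts), `mean_age`, `config`,
#'   `n_obs`.
#' @export
fit_growth <- function(data, config = mcmc_config(), quiet = TRUE) {
  stopifnot(inherits(config, "mcmc_config"))
  data <- as_tibble(data)
  needed <- c("river", "location", "history", "sex", "age", "length")
  miss_col <- setdiff(needed, names(data))
  if (length(miss_col))
    abort(sprintf("data lacks column(s): %s", paste(miss_col, collapse = ", ")))
  if (!all(data$location %in% c("north", "south")))
    abort("`location` must be 'north' or 'south'.")
  if (!all(data$history %in% c("historical", "contemporary")))
    abort("`history` must be 'historical' or 'contemporary'.")
  if (!all(data$sex %in% c("female", "male")))
    abort("`sex` must be 'female' or 'male'.")
  if (anyNA(data$age) || anyNA(data$length))
    abort("age and length must be complete.")
  rivers <- data |> distinct(.data$river, .data$location) |> arrange(.data$river)
  if (anyDuplicated(rivers$river))
    abort("a river maps to more than one location.")
  if (nrow(rivers) < 2) abort("need at least two rivers.")
  for (lv in c("north", "south")) if (!lv %in% rivers$location)
    abort(sprintf("no river in location '%s'.", lv))
  for (hv in c("historical", "contemporary")) if (!hv %in% data$history)
    abort(sprintf("no records with history '%s'.", hv))

  mean_age <- mean(data$age)
  sdL <- sd(data$length)
  if (!is.finite(sdL) || sdL == 0) sdL <- 1
  jd <- list(
    y = data$length,
    agec = data$age - mean_age,
    sex = as.integer(data$sex == "male"),
    contemp = as.integer(data$history == "contemporary"),
    river = match(data$river, rivers$river),
    loc = 1L + as.integer(data$location == "south"),
    southj = as.integer(rivers$location == "south"),
    N = nrow(data), J = nrow(rivers),
    A = config$prior_scale_mult * sdL,
    pv = (config$prior_mean_sd_mult * sdL)^-2
  )
  # start scales at data-plausible values rather than draws from the
  # heavy-tailed prior; chains then need little warmup to forget the start
  base_init <- list(
    b0c = mean(data$length), b1 = 0, b3 = 0, mu_b2 = 0, rho = 0,
    ptau0 = sdL^-2, ptau1 = (0.1 * sdL)^-2,
    prec_b2 = sdL^-2, prec = (0.5 * sdL)^-2
  )
  inits <- lapply(seq_len(config$chains), function(ch) {
    ini <- base_init
    if (!is.null(config$seed)) {
      ini$.RNG.name <- "base::Mersenne-Twister"
      ini$.RNG.seed <- (as.integer(config$seed) * 100L + ch) %% 2147483647L
    }
    ini
  })
  loaded <- try(rjags::load.module("glm", quiet = TRUE), silent = TRUE)
  run <- function() {
    jm <- rjags::jags.model(textConnection(.growth_model_string), data = jd,
                            inits = inits, n.chains = config$chains,
                            n.adapt = config$adapt, quiet = TRUE)
    stats::update(jm, config$n_warmup, progress.bar = "none")
    rjags::coda.samples(
      jm, c("b0c", "b1", "b3", "b4", "b5", "mu_b2", "sigma", "tau0", "tau1",
            "rho", "sig_b2", "uv1", "uv2", "b2", "d"),
      n.iter = config$n_iter - config$n_warmup, thin = config$thin,
      progress.bar = "none")
  }
  samp <- if (quiet) suppressWarnings(run()) else run()

  J <- nrow(rivers)
  rn <- rivers$river
  # transform each chain's matrix to original-scale, named parameters
  trans <- lapply(samp, function(m) {
    m <- as.matrix(m)
    out <- cbind(
      beta0 = m[, "b0c"] - m[, "b1"] * mean_age,
      beta1 = m[, "b1"],
      beta3 = m[, "b3"],
      beta4 = m[, "b4"],
      beta5 = m[, "b5"],
      mu_beta2 = m[, "mu_b2"],
      sigma = m[, "sigma"],
      tau0 = m[, "tau0"],
      tau1 = m[, "tau1"],
      rho = m[, "rho"],
      sigma_beta2 = m[, "sig_b2"],
      d_north = m[, "d[1]"],
      d_south = m[, "d[2]"]
    )
    for (j in seq_len(J)) {
      uv1 <- m[, sprintf("uv1[%d]", j)]
      uv2 <- m[, sprintf("uv2[%d]", j)]
      u1 <- uv2 - m[, "b1"]
      u0c <- uv1 - m[, "b0c"] - m[, "b3"] * jd$southj[j]
      out <- cbind(out,
        setNames(data.frame(uv1, uv2, u0c - u1 * mean_age, u1, m[, sprintf("b2[%d]", j)]),
                 paste0(c("uv1_", "uv2_", "u0_", "u1_", "beta2_"), rn[j])))
    }
    as.matrix(out)
  })

  report_terms <- c("beta0", "beta1", "beta3", "beta4", "beta5", "mu_beta2",
                    "sigma", "tau0", "tau1", "rho", "sigma_beta2")
  summ <- purrr::map_dfr(colnames(trans[[1]]), function(term) {
    per_chain <- lapply(trans, function(m) m[, term])
    .summarize_chains(per_chain, term)
  })

  bad <- summ |>
    filter(.data$term %in% report_terms,
           .data$rhat >= 1.01 | .data$ess <= 1000)
  if (nrow(bad))
    warn(sprintf(
      "convergence below the reporting bar (R-hat < 1.01, ESS > 1000) for: %s",
      paste(sprintf("%s (rhat %.3f, ess %.0f)", bad$term, bad$rhat, bad$ess),
            collapse = "; ")))

  draws <- purrr::map_dfr(seq_along(trans), function(ch)
    bind_cols(tibble(chain = ch, iter = seq_len(nrow(trans[[ch]]))),
              as_tibble(trans[[ch]])))

  structure(
    list(draws = draws,
         summary = summ,
         rivers = rivers,
         cells = count(data, .data$location, .data$history),
         mean_age = mean_age,
         config = config,
         n_obs = nrow(data)),
    class = "growth_fit"
  )
}

# posterior summary + convergence diagnostics from a list of per-chain
# draws. Heavy-tailed quantities (half-Cauchy scales with few groups) make
# the classic Gelman-Rubin statistic noisy even when chains agree, so the
# rank-normalized split versions of R-hat and bulk ESS are used
# (Vehtari, Gelman, Simpson, Carpenter & Buerkner 2021).
.summarize_chains <- function(per_chain, term) {
  x <- unlist(per_chain, use.names = FALSE)
  splits <- unlist(lapply(per_chain, function(v) {
    h <- floor(length(v) / 2)
    list(v[seq_len(h)], v[h + seq_len(h)])
  }), recursive = FALSE)
  n <- min(lengths(splits))
  z_all <- qnorm((rank(unlist(lapply(splits, function(v) v[seq_len(n)]))) - 3 / 8) /
                   (length(splits) * n + 1 / 4))
  zs <- split(z_all, rep(seq_along(splits), each = n))
  m <- length(zs)
  W <- mean(vapply(zs, var, numeric(1)))
  B_over_n <- var(vapply(zs, mean, numeric(1)))
  rhat <- if (W > 0) sqrt(((n - 1) / n * W + B_over_n) / W) else 1
  ess <- sum(coda::effectiveSize(coda::mcmc.list(lapply(zs, coda::mcmc))))
  tibble(
    term = term,
    mean = mean(x), sd = sd(x),
    ci_lower = unname(quantile(x, 0.025)),
    ci_upper = unname(quantile(x, 0.975)),
    rhat = rhat,
    ess = ess
  )
}

#' @export
print.growth_fit <- function(x, ...) {
  cat(sprintf("<growth_fit> %d observations, %d rivers, %d chains x %d retained draws\n",
              x$n_obs, nrow(x$rivers), x$config$chains,
              nrow(x$draws) / x$config$chains))
  print(filter(x$summary, !startsWith(.data$term, "uv")), n = 30)
  invisible(x)
}

#' @describeIn fit_growth Broom-style coefficient table (fixed effects,
#'   scales and river effects) with credible intervals and diagnostics.
#' @param x A `growth_fit`.
#' @param ... Ignored.
#' @exportS3Method generics::tidy
#' @export
tidy.growth_fit <- function(x, ...) {
  x$summary |>
    filter(!startsWith(.data$term, "uv")) |>
    transmute(term = .data$term, estimate = .data$mean, std.error = .data$sd,
              conf.low = .data$ci_lower, conf.high = .data$ci_upper,
              rhat = .data$rhat, ess = .data$ess)
}

#' @describeIn fit_growth One-row model overview.
#' @exportS3Method generics::glance
#' @export
glance.growth_fit <- function(x, ...) {
  rep_terms <- c("beta0", "beta1", "beta3", "beta4", "beta5", "mu_beta2",
                 "sigma", "tau0", "tau1", "rho", "sigma_beta2")
  s <- filter(x$summary, .data$term %in% rep_terms)
  tibble(
    nobs = x$n_obs, n_rivers = nrow(x$rivers),
    chains = x$config$chains, n_draws = nrow(x$draws),
    max_rhat = max(s$rhat, na.rm = TRUE), min_ess = min(s$ess),
    sigma = x$summary$mean[x$summary$term == "sigma"]
  )
}

# ---- derived posterior quantities -----------------------------------------

.posterior_draws <- function(value, chain, name) {
  structure(list(value = value, chain = chain, name = name),
            class = "posterior_draws")
}

#' @export
print.posterior_draws <- function(x, ...) {
  q <- quantile(x$value, c(0.025, 0.975))
  cat(sprintf("<posterior_draws> %s: mean %.1f, 95%% CI [%.1f, %.1f] (%d draws)\n",
              x$name, mean(x$value), q[1], q[2], length(x$value)))
  invisible(x)
}

#' @exportS3Method generics::tidy
#' @export
tidy.posterior_draws <- function(x, ...) {
  per_chain <- split(x$value, x$chain)
  s <- .summarize_chains(per_chain, x$name)
  s |>
    transmute(term = .data$term, estimate = .data$mean, std.error = .data$sd,
              conf.low = .data$ci_lower, conf.high = .data$ci_upper,
              rhat = .data$rhat, ess = .data$ess,
              prob_below_zero = mean(x$value < 0))
}

.check_cell <- function(fit, location, history) {
  n <- fit$cells |>
    filter(.data$location == !!location, .data$history == !!history) |>
    pull(.data$n)
  if (length(n) == 0 || n == 0)
    abort(sprintf("design cell %s x %s has no observations; the requested quantity is not identified.",
                  location, history))
}

#' Posterior predicted length at a given age
#'
#' For each retained draw, the predicted mean length of a fish of the
#' given age, location and period: the fixed effects plus the average of
#' the location's river intercept/slope deviations, plus the mean sex
#' effect weighted by `sex_mix` (0.5 = an even sex mix; 0 = female,
#' 1 = male).
#'
#' @param fit A [fit_growth()] object.
#' @param location `"north"` or `"south"`.
#' @param history `"historical"` or `"contemporary"`.
#' @param age Age in years (default 11, the reference age of this
#'   analysis).
#' @param sex_mix Weight on the male effect (default 0.5).
#' @return A `posterior_draws` object (draw vector plus chain ids);
#'   `tidy()` it for mean, credible interval and diagnostics.
#' @export
predict_age11 <- function(fit, location, history, age = 11, sex_mix = 0.5) {
  stopifnot(inherits(fit, "growth_fit"))
  if (!location %in% c("north", "south")) abort("unknown location.")
  if (!history %in% c("historical", "contemporary")) abort("unknown history.")
  .check_cell(fit, location, history)
  rn <- fit$rivers$river[fit$rivers$location == location]
  if (!length(rn)) abort(sprintf("location '%s' has no rivers.", location))
  d <- fit$draws
  uv1 <- rowMeans(as.matrix(d[paste0("uv1_", rn)]))
  uv2 <- rowMeans(as.matrix(d[paste0("uv2_", rn)]))
  dloc <- if (location == "south") d$d_south else d$d_north
  value <- uv1 + uv2 * (age - fit$mean_age) +
    dloc * (history == "contemporary") +
    d$mu_beta2 * sex_mix
  .posterior_draws(value, d$chain,
                   sprintf("length_age%g_%s_%s", age, location, history))
}

#' Posterior decline in predicted length between periods
#'
#' Historical minus contemporary predicted length at the given age, per
#' draw; positive values mean fish of that age are now smaller.
#'
#' @inheritParams predict_age11
#' @return A `posterior_draws` object.
#' @export
period_decline <- function(fit, location, age = 11, sex_mix = 0.5) {
  h <- predict_age11(fit, location, "historical", age, sex_mix)
  ct <- predict_age11(fit, location, "contemporary", age, sex_mix)
  .posterior_draws(h$value - ct$value, h$chain,
                   sprintf("decline_age%g_%s", age, location))
}

#' South-minus-north difference in period declines
#'
#' The difference-in-differences contrast: (southern decline in predicted
#' length between periods) minus (northern decline), per draw. A positive
#' value means the south lost more length-at-age than the north. The
#' river-level terms cancel, so this equals \eqn{-\beta_5} draw for draw.
#'
#' @inheritParams predict_age11
#' @return A `posterior_draws` object; its `tidy()` includes
#'   `prob_below_zero`, the posterior mass of the contrast below zero.
#' @export
contrast_south_minus_north <- function(fit, age = 11, sex_mix = 0.5) {
  s <- period_decline(fit, "south", age, sex_mix)
  n <- period_decline(fit, "north", age, sex_mix)
  .posterior_draws(s$value - n$value, s$chain,
                   sprintf("contrast_south_minus_north_age%g", age))
}
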