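#' Configuration for the length-at-age generator
#'
#' True parameter values for the hierarchical length-at-age model: a grand
#' mean and age slope, correlated river-level intercept/slope deviations,
#' river-level sex effects around a common mean, fixed effects of location
#' (south vs north reference), history (contemporary vs historical
#' reference) and their interaction, and residual scale. Defaults encode
#' the study conditions this package's analyses target: a 24 mm decline in
#' age-11 length in the north (`beta4 = -24`), a 40 mm decline in the south
#' (`beta4 + beta5 = -40`), hence a 16 mm south-minus-north
#' difference-in-differences, with walleye-realistic size, growth, and
#' sex-dimorphism values.
#'
#' @param rivers Tibble with columns `river` and `location`
#'   (`"north"`/`"south"`); default is one northern and three southern
#'   rivers.
#' @param n_per_cell Records per river x history x sex cell (default 125,
#'   i.e. 500 per river).
#' @param ages Integer vector of ages sampled uniformly.
#' @param beta0 Grand-mean intercept (mm).
#' @param beta1 Mean age slope (mm/yr).
#' @param beta3 Location effect, south vs north (mm).
#' @param beta4 History effect, contemporary vs historical (mm).
#' @param beta5 Location x history interaction (mm).
#' @param mu_beta2,sigma_beta2 Mean and scale of river-level sex (male)
#'   effects (mm); sex is coded 0 = female (reference), 1 = male.
#' @param tau0,tau1,rho Scales and correlation of river intercept/slope
#'   deviations.
#' @param sigma Residual scale (mm); `0` gives noiseless lengths.
#' @param seed Optional integer seed.
#' @return A list of class `growth_sim_config`.
#' @export
growth_sim_config <- function(rivers = tibble(
                                river = c("Takwa", "Chalifour", "Perch", "Icon"),
                                location = c("north", "south", "south", "south")),
                              n_per_cell = 125, ages = 2:19,
                              beta0 = 280, beta1 = 20, beta3 = 10,
                              beta4 = -24, beta5 = -16,
                              mu_beta2 = 40, sigma_beta2 = 10,
                              tau0 = 20, tau1 = 3, rho = 0,
                              sigma = 20, seed = NULL) {
  rivers <- as_tibble(rivers)
  if (!all(c("river", "location") %in% names(rivers)))
    abort("`rivers` needs columns `river` and `location`.")
  if (!all(rivers$location %in% c("north", "south")))
    abort("`location` must be 'north' or 'south'.")
  if (!all(c("north", "south") %in% rivers$location))
    abort("need at least one river per location.")
  if (sigma < 0 || tau0 < 0 || tau1 < 0 || sigma_beta2 < 0)
    abort("scales must be non-negative.")
  if (abs(rho) > 1) abort("`rho` must be in [-1, 1].")
  if (any(n_per_cell < 0)) abort("`n_per_cell` must be non-negative.")
  structure(
    list(rivers = rivers, n_per_cell = n_per_cell, ages = ages,
         beta0 = beta0, beta1 = beta1, beta3 = beta3, beta4 = beta4,
         beta5 = beta5, mu_beta2 = mu_beta2, sigma_beta2 = sigma_beta2,
         tau0 = tau0, tau1 = tau1, rho = rho, sigma = sigma, seed = seed),
    class = "growth_sim_config"
  )
}

#' Simulate a length-at-age dataset
#'
#' Draws river-level random effects and per-fish lengths from the
#' hierarchical model
#' \deqn{\mu = \beta_0 + u_{0j} + \beta_{2j}\,\mathrm{sex} +
#'   (\beta_1 + u_{1j})\,\mathrm{age} + \beta_3\,\mathrm{south} +
#'   \beta_4\,\mathrm{contemp} + \beta_5\,\mathrm{south \times contemp},
#'   \quad \mathrm{Length} \sim N(\mu, \sigma).}
#'
#' `n_per_cell` may be a single number or a function
#' `(river, history, sex) -> n`, allowing unbalanced or empty design cells.
#'
#' @param config A [growth_sim_config()].
#' @return A list with:
#'   * `data`: tibble with `river`, `location`, `history`, `sex`, `age`,
#'     `length` (a growth dataset as consumed by [fit_growth()]);
#'   * `truth`: the config plus the realized river effects (`u0`, `u1`,
#'     `beta2j`) and the implied age-11 declines and south-minus-north
#'     contrast.
#' @export
simulate_growth <- function(config) {
  stopifnot(inherits(config, "growth_sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  rv <- config$rivers
  J <- nrow(rv)
  # correlated river deviations via Cholesky of the 2x2 covariance
  z <- matrix(rnorm(2 * J), J, 2)
  u0 <- config$tau0 * z[, 1]
  u1 <- config$tau1 * (config$rho * z[, 1] + sqrt(1 - config$rho^2) * z[, 2])
  beta2j <- rnorm(J, config$mu_beta2, config$sigma_beta2)

  cells <- tidyr::expand_grid(
    river = rv$river,
    history = c("historical", "contemporary"),
    sex = c("female", "male")
  )
  n_fun <- if (is.function(config$n_per_cell)) {
    config$n_per_cell
  } else {
    function(river, history, sex) config$n_per_cell
  }
  cells$n <- purrr::pmap_int(cells, function(river, history, sex)
    as.integer(n_fun(river, history, sex)))
  dat <- tidyr::uncount(cells, weights = .data$n)
  dat <- dat |>
    left_join(rv, by = "river") |>
    mutate(
      age = sample(config$ages, n(), replace = TRUE),
      j = match(.data$river, rv$river),
      sex01 = as.integer(.data$sex == "male"),
      south = as.integer(.data$location == "south"),
      contemp = as.integer(.data$history == "contemporary")
    )
  mu <- config$beta0 + u0[dat$j] + beta2j[dat$j] * dat$sex01 +
    (config$beta1 + u1[dat$j]) * dat$age +
    config$beta3 * dat$south + config$beta4 * dat$contemp +
    config$beta5 * dat$south * dat$contemp
  dat$length <- if (config$sigma > 0) rnorm(nrow(dat), mu, config$sigma) else mu

  truth <- c(
    unclass(config)[c("beta0", "beta1", "beta3", "beta4", "beta5",
                      "mu_beta2", "sigma_beta2", "tau0", "tau1", "rho", "sigma")],
    list(
      river_effects = tibble(river = rv$river, location = rv$location,
                             u0 = u0, u1 = u1, beta2j = beta2j),
      decline_north = -config$beta4,
      decline_south = -(config$beta4 + config$beta5),
      contrast_south_minus_north = -config$beta5,
      config = config
    )
  )
  list(
    data = dat |>
      select("river", "location", "history", "sex", "age", "length") |>
      as_tibble(),
    truth = truth
  )
}
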