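test_that("JND follows the closed form qnorm(0.75) * sigma", {
  fit10 <- structure(list(mu = 0, sigma = 10), class = "psychometric_fit")
  pj <- derive_pse_jnd(fit10)
  expect_equal(unname(pj["jnd"]), 6.7449, tolerance = 1e-4)
  expect_equal(unname(pj["pse"]), 0)
  fit20 <- structure(list(mu = 3, sigma = 20), class = "psychometric_fit")
  expect_equal(derive_pse_jnd(fit20)[["jnd"]], 2 * pj[["jnd"]])
})

test_that("the Bernoulli MLE agrees with a probit GLM oracle", {
  x <- rep(design_levels_pct(), each = 20)
  for (s in 1:8) {
    mu <- c(-15, -5, 0, 5)[(s %% 4) + 1]
    r <- with_seed_local(100 + s, stats::rbinom(length(x), 1, stats::pnorm((x - mu) / 22)))
    if (length(unique(r)) < 2) next
    fit <- fit_cumulative_gaussian(x, r)
    g <- suppressWarnings(stats::glm(r ~ x, family = stats::binomial("probit")))
    mu_glm <- -stats::coef(g)[[1]] / stats::coef(g)[[2]]
    sd_glm <- 1 / stats::coef(g)[[2]]
    expect_equal(fit$mu, mu_glm, tolerance = 0.02)
    expect_equal(fit$sigma, sd_glm, tolerance = 0.02)
    expect_gte(fit$loglik, as.numeric(stats::logLik(g)) - 1e-3)
  }
})

test_that("recovery error at the design's trial counts matches the information bound", {
  # 100 observers at sigma = 20: the Fisher information of 7x20 binary
  # trials bounds se(mu) at ~3.1, so the median error sits near 2.1 and
  # must not exceed ~1.3x that bound for an efficient estimator.
  x <- rep(design_levels_pct(), each = 20)
  errs <- with_seed_local(2024, vapply(1:100, function(i) {
    mu <- stats::rnorm(1, 0, 5)
    r <- stats::rbinom(length(x), 1, stats::pnorm((x - mu) / 20))
    fit_cumulative_gaussian(x, r)$mu - mu
  }, numeric(1)))
  expect_lt(stats::median(abs(errs)), 1.3 * 2.1)
  expect_lt(abs(stats::median(errs)), 1.0) # no systematic bias
})

test_that("large samples recover the generating parameters", {
  x <- rep(design_levels_pct(), each = 1500)
  r <- with_seed_local(7, stats::rbinom(length(x), 1, stats::pnorm((x + 12.75) / 20)))
  fit <- fit_cumulative_gaussian(x, r)
  expect_lt(abs(fit$mu - -12.75), 1)
  expect_lt(abs(fit$sigma - 20), 1)
  expect_true(fit$converged)
  expect_false(fit$flagged)
})

test_that("symmetric balanced data give a PSE near zero", {
  x <- rep(design_levels_pct(), each = 200)
  r <- with_seed_local(11, stats::rbinom(length(x), 1, stats::pnorm(x / 20)))
  fit <- fit_cumulative_gaussian(x, r)
  expect_lt(abs(fit$mu), 0.5)
})

test_that("degenerate inputs error and separation is flagged, never silent", {
  x <- rep(c(-20, 0, 20), each = 10)
  expect_error(fit_cumulative_gaussian(x, rep(1, 30)), "identical")
  expect_error(fit_cumulative_gaussian(rep(0, 30), rep(c(0, 1), 15)), "distinct")
  # complete separation drives sigma to its lower bound and is flagged
  r_sep <- as.integer(x > 0 | (x == 0 & rep(c(TRUE, FALSE), 15)))
  fit <- fit_cumulative_gaussian(x, r_sep)
  expect_true(fit$flagged)
  expect_match(fit$flag_reason, "lower bound")
})

test_that("fitting in ms or percent units gives equivalent PSE and JND", {
  std <- 600
  xp <- rep(design_levels_pct(), each = 20)
  r <- with_seed_local(21, stats::rbinom(length(xp), 1, stats::pnorm((xp + 10) / 18)))
  fp <- fit_cumulative_gaussian(xp, r)
  xm <- std * (1 + xp / 100)
  fm <- fit_cumulative_gaussian(xm, r, sigma_bounds = c(3, 1200))
  expect_equal(100 * (fm$mu - std) / std, fp$mu, tolerance = 0.02)
  expect_equal(100 * fm$sigma / std, fp$sigma, tolerance = 0.02)
})

test_that("the fitted likelihood never falls below the moment initializer's", {
  x <- rep(design_levels_pct(), each = 20)
  for (s in 31:36) {
    r <- with_seed_local(s, stats::rbinom(length(x), 1, stats::pnorm((x - 5) / 30)))
    fit <- fit_cumulative_gaussian(x, r)
    expect_gte(fit$loglik, fit$loglik_init)
  }
})

test_that("least-squares mode exists and lands near the MLE on clean data", {
  x <- rep(design_levels_pct(), each = 100)
  r <- with_seed_local(41, stats::rbinom(length(x), 1, stats::pnorm((x - 4) / 25)))
  f1 <- fit_cumulative_gaussian(x, r, method = "ml")
  f2 <- fit_cumulative_gaussian(x, r, method = "lsq")
  expect_equal(f2$mu, f1$mu, tolerance = 0.1)
  expect_equal(f2$sigma, f1$sigma, tolerance = 0.1)
})

test_that("adaptation effects subtract PSEs and guard the standard", {
  mk <- function(mu, std) structure(list(mu = mu, sigma = 15, standard_ms = std,
                                         participant = NA_character_),
                                    class = "psychometric_fit")
  expect_equal(adaptation_effect(mk(-5, 600), mk(-5, 600)), 0)
  expect_equal(adaptation_effect(mk(-12.75, 600), mk(3.74, 600)), -16.49,
               tolerance = 1e-10)
  expect_lt(abs(adaptation_effect(mk(-7.02, 1200), mk(-0.127, 1200)) - -6.89), 0.01)
  expect_error(adaptation_effect(mk(-5, 600), mk(0, 1200)), "standard")
})
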