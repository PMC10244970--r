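#' Fit a cumulative-Gaussian psychometric function to 2AFC responses
#'
#' Fits `P(comparison judged longer) = lapse/2 + (1 - lapse) *
#' pnorm((x - mu) / sigma)` to binary trial data by maximizing the
#' Bernoulli log-likelihood over `(mu, sigma)`, with the lapse rate held
#' fixed (0 by default). `x` is the comparison level, conventionally the
#' signed percent difference from the standard duration. A least-squares
#' mode fitting the pooled per-level proportions is available for
#' sensitivity analysis.
#'
#' Optimization is multi-start from a probit-regression initializer (and
#' scale perturbations of it), so the returned log-likelihood is never
#' below the initializer's. `sigma` is bounded to `sigma_bounds`; a fit
#' that ends on a bound (e.g. under complete separation, which drives
#' `sigma` to its lower bound) is returned with `flagged = TRUE`.
#'
#' @param x Comparison levels, one per trial.
#' @param response Binary responses (1 = comparison judged longer).
#' @param lapse Fixed lapse rate in `[0, 0.5)`.
#' @param method `"ml"` (Bernoulli maximum likelihood on trials, default)
#'   or `"lsq"` (least squares on per-level proportions, weighted by trial
#'   counts).
#' @param sigma_bounds Lower and upper bounds for `sigma`, in the units of
#'   `x`.
#' @param standard_ms,participant,condition Optional metadata carried on
#'   the fit (used by [adaptation_effect()] and the analysis pipeline).
#' @return An object of class `psychometric_fit` with elements `mu`,
#'   `sigma`, `loglik`, `n_trials`, `converged`, `flagged`, `lapse`,
#'   `method`, and the metadata.
#' @examples
#' set.seed(1)
#' x <- rep(c(-66.67, -33.33, -16.67, 0, 16.67, 33.33, 66.67), each = 20)
#' r <- rbinom(length(x), 1, pnorm((x - 5) / 15))
#' fit <- fit_cumulative_gaussian(x, r)
#' derive_pse_jnd(fit)
#' @export
fit_cumulative_gaussian <- function(x, response, lapse = 0,
                                    method = c("ml", "lsq"),
                                    sigma_bounds = c(0.5, 200),
                                    standard_ms = NA_real_,
                                    participant = NA_character_,
                                    condition = NA_character_) {
  method <- match.arg(method)
  if (length(x) != length(response)) stop("x and response lengths differ")
  if (!all(response %in% c(0, 1))) stop("responses must be 0/1")
  if (lapse < 0 || lapse >= 0.5) stop("lapse must be in [0, 0.5)")
  if (length(unique(x)) < 2) {
    stop("degenerate input: need at least 2 distinct comparison levels")
  }
  if (length(unique(response)) < 2) {
    stop("degenerate input: all responses identical, psychometric function unidentifiable")
  }

  # aggregate to binomial counts per level: the Bernoulli likelihood only
  # depends on (successes, trials) at each comparison level
  lev <- sort(unique(x))
  nrep <- vapply(lev, function(l) sum(x == l), numeric(1))
  kk <- vapply(lev, function(l) sum(response[x == l]), numeric(1))
  phat <- kk / nrep
  nll <- function(par) {
    p <- lapse / 2 + (1 - lapse) * stats::pnorm((lev - par[1]) / par[2])
    p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
    -sum(kk * log(p) + (nrep - kk) * log(1 - p))
  }
  obj <- if (method == "ml") nll else function(par) {
    pm <- lapse / 2 + (1 - lapse) * stats::pnorm((lev - par[1]) / par[2])
    sum(nrep * (phat - pm)^2)
  }

  # moment-based initializer: probit-transformed linear regression
  zc <- stats::qnorm(pmin(pmax(phat, 0.02), 0.98))
  init <- tryCatch({
    cf <- stats::coef(stats::lm(zc ~ lev, weights = nrep))
    if (is.na(cf[2]) || cf[2] <= 0) NULL else unname(c(-cf[1] / cf[2], 1 / cf[2]))
  }, error = function(e) NULL)
  if (is.null(init)) init <- c(stats::median(x), diff(range(x)) / 4)
  init[2] <- min(max(init[2], sigma_bounds[1]), sigma_bounds[2])
  span <- diff(range(x))
  lower <- c(min(x) - 2 * span, sigma_bounds[1])
  upper <- c(max(x) + 2 * span, sigma_bounds[2])
  init[1] <- min(max(init[1], lower[1]), upper[1])

  starts <- list(init,
                 c(init[1], min(max(init[2] * 3, sigma_bounds[1]), sigma_bounds[2])),
                 c(init[1], min(max(init[2] / 3, sigma_bounds[1]), sigma_bounds[2])))
  best <- NULL
  for (s in starts) {
    res <- tryCatch(
      stats::optim(s, obj, method = "L-BFGS-B", lower = lower, upper = upper),
      error = function(e) NULL
    )
    if (!is.null(res) && (is.null(best) || res$value < best$value)) best <- res
  }
  if (is.null(best)) stop("psychometric fit failed from all starting points")
  mu <- unname(best$par[1])
  sigma <- unname(best$par[2])
  at_bound <- sigma <= sigma_bounds[1] + 1e-8 || sigma >= sigma_bounds[2] - 1e-8
  structure(list(
    mu = mu,
    sigma = sigma,
    loglik = -nll(best$par),
    loglik_init = -nll(init),
    n_trials = length(x),
    converged = best$convergence == 0,
    flagged = at_bound,
    flag_reason = if (at_bound) {
      if (sigma <= sigma_bounds[1] + 1e-8) "sigma at lower bound" else "sigma at upper bound"
    } else {
      NA_character_
    },
    lapse = lapse,
    method = method,
    standard_ms = standard_ms,
    participant = participant,
    condition = condition
  ), class = "psychometric_fit")
}

#' @export
print.psychometric_fit <- function(x, ...) {
  cat(sprintf(
    "<psychometric_fit> mu = %.3f, sigma = %.3f (JND = %.3f), n = %d, logLik = %.2f%s%s\n",
    x$mu, x$sigma, stats::qnorm(0.75) * x$sigma, x$n_trials, x$loglik,
    if (!x$converged) " [not converged]" else "",
    if (x$flagged) sprintf(" [%s]", x$flag_reason) else ""
  ))
  invisible(x)
}

#' PSE and JND of a psychometric fit
#'
#' The point of subjective equality is the 50% point of the fitted
#' function, i.e. `mu`; the just noticeable difference is half the
#' distance between its 25% and 75% points, which for a cumulative
#' Gaussian is `qnorm(0.75) * sigma`.
#'
#' @param fit A [psychometric_fit][fit_cumulative_gaussian].
#' @return Named numeric vector `c(pse, jnd)` in the units of the fitted
#'   comparison levels.
#' @examples
#' # sigma = 10 gives jnd = 6.7449
#' @export
derive_pse_jnd <- function(fit) {
  c(pse = fit$mu, jnd = stats::qnorm(0.75) * fit$sigma)
}

#' Adaptation effect from a pair of fits
#'
#' The adaptation effect is the difference between the adaptation and
#' baseline PSE estimates for the same participant and standard duration,
#' expressed in percent of the standard (negative values indicate
#' perceived compression).
#'
#' @param fit_adapt,fit_baseline Fits from
#'   [fit_cumulative_gaussian()] for the adaptation and baseline
#'   conditions; their `standard_ms` (and `participant`, when set) must
#'   match.
#' @return The effect, `pse_adapt - pse_baseline`.
#' @export
adaptation_effect <- function(fit_adapt, fit_baseline) {
  if (!isTRUE(all.equal(fit_adapt$standard_ms, fit_baseline$standard_ms))) {
    stop("fits have different standard durations")
  }
  if (!is.na(fit_adapt$participant) && !is.na(fit_baseline$participant) &&
      fit_adapt$participant != fit_baseline$participant) {
    stop("fits belong to different participants")
  }
  fit_adapt$mu - fit_baseline$mu
}
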