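#' Population specification for the synthetic experiment
#'
#' Describes the between-participant distribution of psychometric
#' parameters for each cell (condition x standard duration) of the
#' adaptation experiment. Defaults encode the group statistics of the
#' twenty-participant study the package emulates: cell means are the
#' published group means and between-participant standard deviations are
#' `s.e.m. * sqrt(n)`. The 1200 ms JND means are not published as numbers;
#' the defaults (24.0% baseline, 24.5% adaptation, s.e.m. 2) encode the
#' reported finding that discrimination at 1200 ms was essentially
#' unchanged, with a slight numerical increase after adaptation.
#'
#' @param n_participants Number of simulated participants.
#' @param cells Data frame with columns `condition`, `standard_ms`,
#'   `pse_mean`, `pse_sem`, `jnd_mean`, `jnd_sem` (all in percent of the
#'   standard).
#' @param baseline600_pse_jnd_cor Correlation between PSE and JND across
#'   participants in the baseline 600 ms cell (0 by default; set to ~0.67
#'   to emulate the observed coupling between overestimation and
#'   discrimination threshold).
#' @param adapt_mu_cor Correlation between a participant's adaptation-cell
#'   PSEs at the two standards, carried by a shared "adaptability" factor
#'   (participants who adapt strongly do so at both time scales). The
#'   default 0.44 is implied by the published group statistics: with the
#'   printed effect means and s.e.m.s, the paired comparison of the two
#'   standards' effects requires an effect correlation of ~0.48.
#' @param within_standard_cor Correlation between a participant's baseline
#'   and adaptation PSEs at the same standard. The default 0.42 is implied
#'   by the printed effect s.e.m.s (1.78/1.79), which are well below the
#'   values the cell s.e.m.s would give under independence (2.36/2.21).
#'   Setting both correlations to 0 makes all cells independent.
#' @param sem_n Number of participants in the source study whose s.e.m.s
#'   the cell table carries; between-participant SDs are
#'   `sem * sqrt(sem_n)` regardless of how many participants are drawn.
#' @param contaminate If `TRUE`, plant three extreme overestimators in the
#'   baseline 600 ms cell at `outlier_pses`, keeping the remaining
#'   participants' PSEs below the smallest outlier so the three are
#'   unambiguously the highest (they were clearly separated in the
#'   observed data). Used to exercise the exclusion re-analysis.
#' @param outlier_pses Baseline-600 PSE values of the planted outliers.
#' @return An object of class `population_spec`.
#' @export
population_spec <- function(n_participants = 20,
                            cells = default_population_cells(),
                            sem_n = 20,
                            baseline600_pse_jnd_cor = 0,
                            adapt_mu_cor = 0.44,
                            within_standard_cor = 0.42,
                            contaminate = FALSE,
                            outlier_pses = c(11.07, 15.73, 21.73)) {
  stopifnot(is.data.frame(cells))
  need <- c("condition", "standard_ms", "pse_mean", "pse_sem", "jnd_mean", "jnd_sem")
  if (!all(need %in% names(cells))) {
    stop("cells must have columns: ", paste(need, collapse = ", "))
  }
  if (n_participants <= 0) stop("n_participants must be positive")
  if (any(cells$jnd_mean <= 0)) stop("JND means must be positive")
  if (any(cells$pse_sem < 0) || any(cells$jnd_sem < 0)) stop("s.e.m.s must be non-negative")
  structure(list(
    n_participants = n_participants,
    cells = cells,
    sem_n = sem_n,
    baseline600_pse_jnd_cor = baseline600_pse_jnd_cor,
    adapt_mu_cor = adapt_mu_cor,
    within_standard_cor = within_standard_cor,
    contaminate = contaminate,
    outlier_pses = outlier_pses
  ), class = "population_spec")
}

#' @rdname population_spec
#' @export
default_population_cells <- function() {
  data.frame(
    condition = c("baseline", "adaptation", "baseline", "adaptation"),
    standard_ms = c(600, 600, 1200, 1200),
    pse_mean = c(3.74, -12.75, -0.127, -7.02),
    pse_sem = c(1.53, 1.8, 1.08, 1.93),
    jnd_mean = c(23.24, 19.3, 24.0, 24.5),
    jnd_sem = c(1.92, 1.71, 2.0, 2.0)
  )
}

#' Draw per-participant psychometric parameters
#'
#' Samples each participant's true `(mu, sigma)` for every cell from
#' independent normal distributions with the spec's means and
#' between-participant SDs (`s.e.m. * sqrt(n)`), truncating `sigma` above
#' 0.5% (redrawing JNDs that would violate it). The optional baseline-600
#' PSE-JND correlation and outlier contamination of the spec are applied
#' here. Deterministic given `seed`.
#'
#' @param spec A [population_spec()].
#' @param seed Integer seed.
#' @return Data frame with one row per participant x cell: `participant`,
#'   `condition`, `standard_ms`, `mu_pct`, `jnd_pct`, `sigma_pct`.
#' @export
sample_population <- function(spec, seed = 1) {
  n <- spec$n_participants
  sigma_floor <- 0.5
  jnd_floor <- sigma_floor * stats::qnorm(0.75)
  with_local_seed(seed, {
    # shared per-participant adaptability factor couples the two
    # adaptation cells' PSEs at adapt_mu_cor; each adaptation cell is also
    # coupled to its own standard's baseline at within_standard_cor
    shared <- stats::rnorm(n)
    cc <- spec$adapt_mu_cor
    w <- spec$within_standard_cor
    if (w^2 + cc > 1) stop("within_standard_cor^2 + adapt_mu_cor must be <= 1")
    z_base <- list() # baseline z1 per standard, for the adaptation coupling
    rows <- lapply(seq_len(nrow(spec$cells)), function(i) {
      cell <- spec$cells[i, ]
      sd_mu <- cell$pse_sem * sqrt(spec$sem_n)
      sd_jnd <- cell$jnd_sem * sqrt(spec$sem_n)
      is_b600 <- cell$condition == "baseline" && cell$standard_ms == 600
      is_adapt <- cell$condition == "adaptation"
      r <- if (is_b600) spec$baseline600_pse_jnd_cor else 0
      zb <- z_base[[as.character(cell$standard_ms)]]
      draw <- function(m, idx = seq_len(m)) {
        z1 <- stats::rnorm(m)
        if (is_adapt && !is.null(zb)) {
          z1 <- w * zb[idx] + sqrt(cc) * shared[idx] + sqrt(1 - w^2 - cc) * z1
        }
        z2 <- stats::rnorm(m)
        list(z1 = z1,
             mu = cell$pse_mean + sd_mu * z1,
             jnd = cell$jnd_mean + sd_jnd * (r * z1 + sqrt(1 - r^2) * z2))
      }
      d <- draw(n)
      mu <- d$mu
      jnd <- d$jnd
      bad <- which(jnd < jnd_floor)
      while (length(bad) > 0) {
        jnd[bad] <- cell$jnd_mean + sd_jnd * stats::rnorm(length(bad))
        bad <- which(jnd < jnd_floor)
      }
      if (is_b600 && spec$contaminate) {
        k <- length(spec$outlier_pses)
        if (n < k + 2) stop("too few participants to contaminate")
        # keep the bulk well below the smallest outlier: the observed
        # outliers were clearly separated from the rest, and the gap must
        # exceed psychometric fitting noise for the exclusion rule to
        # identify exactly the planted participants. Redraws are joint so
        # any PSE-JND coupling survives the truncation.
        cap <- min(spec$outlier_pses) - 4
        over <- which(mu > cap)
        while (length(over) > 0) {
          rd <- draw(length(over))
          mu[over] <- rd$mu
          jnd[over] <- pmax(rd$jnd, jnd_floor)
          d$z1[over] <- rd$z1
          over <- which(mu > cap)
        }
        # planted overestimators take the JND the coupling predicts for
        # their PSE (the observed outliers also had high thresholds)
        idx <- seq_len(k)
        mu[idx] <- spec$outlier_pses
        if (sd_mu > 0) {
          jnd[idx] <- pmax(jnd_floor,
                           cell$jnd_mean +
                             r * sd_jnd * (spec$outlier_pses - cell$pse_mean) / sd_mu +
                             sqrt(1 - r^2) * sd_jnd * stats::rnorm(k))
          d$z1[idx] <- (mu[idx] - cell$pse_mean) / sd_mu
        }
      }
      if (cell$condition == "baseline") {
        z_base[[as.character(cell$standard_ms)]] <<- d$z1
      }
      data.frame(
        participant = sprintf("P%02d", seq_len(n)),
        condition = cell$condition,
        standard_ms = cell$standard_ms,
        mu_pct = mu,
        jnd_pct = jnd,
        sigma_pct = jnd / stats::qnorm(0.75)
      )
    })
    do.call(rbind, rows)
  })
}

#' Simulate 2AFC trials for a set of observers
#'
#' For every observer row and every comparison level of the design
#' (fractions converted to signed percent of the standard), draws exactly
#' `min_reps` Bernoulli responses with
#' `P(longer) = pnorm((x - mu) / sigma)`. Deterministic given `seed`.
#'
#' @param observers Data frame as returned by [sample_population()].
#' @param design An [experiment_design()].
#' @param seed Integer seed.
#' @return A trial table: `participant`, `condition`, `standard_ms`,
#'   `comparison_pct`, `response`, `rep`.
#' @export
simulate_trials <- function(observers, design = experiment_design(), seed = 1) {
  levels_pct <- round(comparison_levels_pct(design), 2)
  reps <- design$min_reps
  with_local_seed(seed, {
    rows <- lapply(seq_len(nrow(observers)), function(i) {
      o <- observers[i, ]
      p <- stats::pnorm((levels_pct - o$mu_pct) / o$sigma_pct)
      resp <- stats::rbinom(length(levels_pct) * reps, 1, rep(p, each = reps))
      data.frame(
        participant = o$participant,
        condition = o$condition,
        standard_ms = o$standard_ms,
        comparison_pct = rep(levels_pct, each = reps),
        response = resp,
        rep = rep(seq_len(reps), times = length(levels_pct))
      )
    })
    do.call(rbind, rows)
  })
}

#' Simulate a model-driven 2AFC observer
#'
#' Links the channel model to the experimental task. On each trial the
#' standard appears in the adapted location and the comparison in an
#' unadapted location, so in the adaptation condition the standard's
#' perceived duration comes from the adapted model while the comparison's
#' comes from the unadapted model; in the baseline condition both are
#' unadapted. The response is `1` (comparison longer) when the comparison's
#' decoded duration plus Gaussian decision noise exceeds the standard's.
#'
#' @param bank,filter,mapping Model components (see
#'   [predict_perceived_duration()]).
#' @param design An [experiment_design()].
#' @param adaptor Adaptor for the adaptation condition (default the
#'   mixed-frequency flicker).
#' @param decision_noise_pct SD of the decision noise on each interval's
#'   decoded duration, in percent of the standard.
#' @param seed Integer seed.
#' @param participant Participant label written to the table.
#' @return A trial table in the same format as [simulate_trials()].
#' @export
simulate_model_observer <- function(bank, filter, mapping,
                                    design = experiment_design(),
                                    adaptor = flicker_adaptor(),
                                    decision_noise_pct = 20,
                                    seed = 1,
                                    participant = "model") {
  levels_pct <- round(comparison_levels_pct(design), 2)
  reps <- design$min_reps
  decode_cache <- new.env(parent = emptyenv())
  decoded <- function(d, adapted) {
    key <- sprintf("%.6f_%d", d, adapted)
    if (is.null(decode_cache[[key]])) {
      decode_cache[[key]] <- predict_perceived_duration(
        d, if (adapted) adaptor else NULL, bank, filter, mapping
      )
    }
    decode_cache[[key]]
  }
  with_local_seed(seed, {
    rows <- list()
    for (std in design$standards_ms) {
      noise_ms <- decision_noise_pct / 100 * std
      for (cond in c("baseline", "adaptation")) {
        dec_std <- decoded(std, cond == "adaptation")
        for (x in levels_pct) {
          cmp_ms <- std * (1 + x / 100)
          dec_cmp <- decoded(cmp_ms, FALSE)
          e <- stats::rnorm(reps, 0, noise_ms)
          e2 <- stats::rnorm(reps, 0, noise_ms)
          resp <- as.integer(dec_cmp + e > dec_std + e2)
          rows[[length(rows) + 1]] <- data.frame(
            participant = participant,
            condition = cond,
            standard_ms = std,
            comparison_pct = x,
            response = resp,
            rep = seq_len(reps)
          )
        }
      }
    }
    do.call(rbind, rows)
  })
}
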