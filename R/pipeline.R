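#' Load a 2AFC trial table from a delimited text file
#'
#' Reads a CSV of duration-judgement trials into the canonical layout
#' `participant, condition, standard_ms, comparison_pct, response, rep`.
#' Alternative column namings are handled through `column_map`, a named
#' character vector from canonical names to the file's names (e.g.
#' `c(participant = "subj", comparison_pct = "comp")`). Comparison values
#' supplied in milliseconds (either via a `comparison_ms` column/mapping or
#' detected from their scale) are converted to signed percent of the
#' standard.
#'
#' Validation is strict: unknown condition labels, non-binary responses or
#' non-numeric fields raise an error naming the offending rows.
#'
#' @param path CSV file path.
#' @param column_map Optional named character vector renaming columns.
#' @param sep Field separator.
#' @return A validated trial table (data frame).
#' @export
load_trials <- function(path, column_map = NULL, sep = ",") {
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE)
  if (nrow(raw) == 0) stop("no trials found in ", path)
  comparison_in_ms <- FALSE
  if (!is.null(column_map)) {
    if (is.null(names(column_map))) stop("column_map must be a named vector")
    for (canon in names(column_map)) {
      actual <- column_map[[canon]]
      if (!actual %in% names(raw)) {
        stop(sprintf("column '%s' (mapped to '%s') not found", actual, canon))
      }
      names(raw)[names(raw) == actual] <- canon
    }
  }
  if ("comparison_ms" %in% names(raw) && !"comparison_pct" %in% names(raw)) {
    names(raw)[names(raw) == "comparison_ms"] <- "comparison_pct"
    comparison_in_ms <- TRUE
  }
  need <- c("participant", "condition", "standard_ms", "comparison_pct", "response")
  miss <- setdiff(need, names(raw))
  if (length(miss) > 0) stop("missing columns: ", paste(miss, collapse = ", "))
  if (!"rep" %in% names(raw)) raw$rep <- stats::ave(raw$response, raw$participant,
                                                    raw$condition, raw$standard_ms,
                                                    raw$comparison_pct,
                                                    FUN = seq_along)
  bad <- which(!raw$condition %in% c("baseline", "adaptation"))
  if (length(bad) > 0) {
    stop("unknown condition labels at rows: ", paste(utils::head(bad, 10), collapse = ", "))
  }
  bad <- which(!raw$response %in% c(0, 1))
  if (length(bad) > 0) {
    stop("non-binary responses at rows: ", paste(utils::head(bad, 10), collapse = ", "))
  }
  if (!is.numeric(raw$standard_ms) || !is.numeric(raw$comparison_pct)) {
    stop("standard_ms and comparison values must be numeric")
  }
  # heuristic ms detection: percent differences live within roughly +/-100,
  # while millisecond comparisons are positive and of the standard's scale
  if (!comparison_in_ms && all(raw$comparison_pct >= 0) &&
      max(raw$comparison_pct) > 90) {
    comparison_in_ms <- TRUE
  }
  if (comparison_in_ms) {
    raw$comparison_pct <- round(100 * (raw$comparison_pct - raw$standard_ms) /
                                  raw$standard_ms, 2)
  }
  raw[, c("participant", "condition", "standard_ms", "comparison_pct",
          "response", "rep")]
}

#' Per-participant fits and group summaries for every cell
#'
#' Fits a cumulative Gaussian per (participant, condition, standard), then
#' aggregates: per-cell means and standard errors (`sd/sqrt(n)`) of PSE and
#' JND, and the per-participant adaptation effects
#' (`PSE_adaptation - PSE_baseline`, negative = compression). Fits that
#' fail or end flagged are recorded and surfaced; failed fits drop that
#' participant from the affected summaries with a warning, flagged fits
#' are retained.
#'
#' @param trials A trial table (see [load_trials()] /
#'   [simulate_trials()]).
#' @param method,lapse Passed to [fit_cumulative_gaussian()].
#' @return An object of class `condition_summary`: a list with `fits`
#'   (per participant x cell), `summary` (per cell), `effects` (per
#'   participant, wide by standard), and `failures`.
#' @export
summarize_conditions <- function(trials, method = "ml", lapse = 0) {
  if (length(unique(trials$participant)) < 2) {
    stop("need at least 2 participants")
  }
  groups <- split(trials, list(trials$participant, trials$condition,
                               trials$standard_ms), drop = TRUE)
  fits <- lapply(groups, function(sub) {
    fit <- tryCatch(
      fit_cumulative_gaussian(sub$comparison_pct, sub$response,
                              lapse = lapse, method = method,
                              standard_ms = sub$standard_ms[1],
                              participant = sub$participant[1],
                              condition = sub$condition[1]),
      error = function(e) e
    )
    if (inherits(fit, "error")) {
      data.frame(participant = sub$participant[1], condition = sub$condition[1],
                 standard_ms = sub$standard_ms[1], pse = NA_real_, jnd = NA_real_,
                 sigma = NA_real_, loglik = NA_real_, converged = FALSE,
                 flagged = TRUE, note = conditionMessage(fit))
    } else {
      pj <- derive_pse_jnd(fit)
      data.frame(participant = sub$participant[1], condition = sub$condition[1],
                 standard_ms = sub$standard_ms[1], pse = pj[["pse"]],
                 jnd = pj[["jnd"]], sigma = fit$sigma, loglik = fit$loglik,
                 converged = fit$converged, flagged = fit$flagged,
                 note = if (fit$flagged) fit$flag_reason else "")
    }
  })
  fits <- do.call(rbind, c(fits, list(make.row.names = FALSE)))
  failures <- fits[is.na(fits$pse), ]
  if (nrow(failures) > 0) {
    warning(sprintf("%d cell fit(s) failed and were dropped from summaries",
                    nrow(failures)))
  }
  ok <- fits[!is.na(fits$pse), ]
  agg <- do.call(rbind, lapply(split(ok, list(ok$condition, ok$standard_ms),
                                     drop = TRUE), function(g) {
    data.frame(condition = g$condition[1], standard_ms = g$standard_ms[1],
               n = nrow(g),
               pse_mean = mean(g$pse), pse_sem = stats::sd(g$pse) / sqrt(nrow(g)),
               jnd_mean = mean(g$jnd), jnd_sem = stats::sd(g$jnd) / sqrt(nrow(g)))
  }))
  rownames(agg) <- NULL
  standards <- sort(unique(ok$standard_ms))
  parts <- sort(unique(ok$participant))
  eff <- data.frame(participant = parts)
  for (std in standards) {
    col <- paste0("effect_", std)
    eff[[col]] <- vapply(parts, function(p) {
      a <- ok$pse[ok$participant == p & ok$condition == "adaptation" &
                    ok$standard_ms == std]
      b <- ok$pse[ok$participant == p & ok$condition == "baseline" &
                    ok$standard_ms == std]
      if (length(a) == 1 && length(b) == 1) a - b else NA_real_
    }, numeric(1))
  }
  structure(list(fits = fits, summary = agg, effects = eff,
                 failures = failures),
            class = "condition_summary")
}

#' @export
print.condition_summary <- function(x, ...) {
  cat("<condition_summary>\n")
  print(x$summary, digits = 4)
  invisible(x)
}

#' Classical paired-samples t-test
#'
#' Thin wrapper around [stats::t.test()] on paired observations, returning
#' the statistic, degrees of freedom (`n - 1`) and the two-sided p-value.
#'
#' @param x,y Paired measurements (equal length, at least 2 complete
#'   pairs).
#' @return A list with `t`, `df`, `p`.
#' @export
paired_t_test <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  keep <- stats::complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 2) stop("need at least 2 complete pairs")
  if (stats::sd(x - y) == 0) {
    if (all(x == y)) return(list(t = 0, df = length(x) - 1, p = 1))
    stop("zero variance of paired differences")
  }
  res <- stats::t.test(x, y, paired = TRUE)
  list(t = unname(res$statistic), df = unname(res$parameter),
       p = res$p.value)
}

#' Pearson correlation
#'
#' Sample Pearson correlation with explicit degenerate-input errors.
#'
#' @param x,y Numeric vectors of equal length (at least 3).
#' @return The correlation coefficient `r`.
#' @export
pearson_correlation <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  keep <- stats::complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3) stop("need at least 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance: correlation undefined")
  }
  stats::cor(x, y)
}

#' Re-analysis excluding the highest baseline-600 overestimators
#'
#' Ranks participants by their baseline PSE at the short standard, removes
#' the `k` highest, and recomputes all summaries on the remaining
#' participants. An exact tie at the cut boundary is an error (supply an
#' explicit id list by subsetting the trials instead).
#'
#' @param trials A trial table.
#' @param k Number of participants to exclude (`k = 0` reproduces
#'   [summarize_conditions()]).
#' @param standard_ms The standard whose baseline PSEs define the ranking.
#' @param ... Passed to [summarize_conditions()].
#' @return A `condition_summary` with an extra `excluded` data frame
#'   (`participant`, `baseline_pse`).
#' @export
exclusion_reanalysis <- function(trials, k = 3, standard_ms = 600, ...) {
  full <- summarize_conditions(trials, ...)
  base <- full$fits[full$fits$condition == "baseline" &
                      full$fits$standard_ms == standard_ms &
                      !is.na(full$fits$pse), ]
  if (nrow(base) < k + 2) stop("too few participants for exclusion re-analysis")
  ord <- order(base$pse, decreasing = TRUE)
  if (k > 0) {
    if (k < nrow(base) && base$pse[ord[k]] == base$pse[ord[k + 1]]) {
      stop("tie at the exclusion boundary: supply an explicit participant list")
    }
    drop_ids <- base$participant[ord[seq_len(k)]]
  } else {
    drop_ids <- character(0)
  }
  kept <- trials[!trials$participant %in% drop_ids, ]
  out <- summarize_conditions(kept, ...)
  out$excluded <- data.frame(participant = base$participant[ord[seq_len(k)]],
                             baseline_pse = base$pse[ord[seq_len(k)]])
  out
}

#' Count participants with stronger sub-second compression
#'
#' Counts how many participants show a more negative adaptation effect
#' (stronger compression) at the shorter standard than at the longer one.
#' Participants missing either cell are skipped with a warning.
#'
#' @param effects The `effects` data frame of a
#'   [condition_summary][summarize_conditions] (columns `effect_<short>`
#'   and `effect_<long>`).
#' @param standards The two standards, shorter first.
#' @return Integer count, with attribute `n` = number of complete
#'   participants.
#' @export
count_stronger_effect <- function(effects, standards = c(600, 1200)) {
  cs <- paste0("effect_", standards[1])
  cl <- paste0("effect_", standards[2])
  if (!all(c(cs, cl) %in% names(effects))) {
    stop("effects table lacks the requested standards")
  }
  keep <- stats::complete.cases(effects[[cs]], effects[[cl]])
  if (any(!keep)) {
    warning(sprintf("%d participant(s) missing a cell were skipped", sum(!keep)))
  }
  n <- sum(keep)
  count <- sum(effects[[cs]][keep] < effects[[cl]][keep])
  structure(as.integer(count), n = n)
}

#' Full group-level analysis battery
#'
#' Convenience wrapper running the whole analysis on a trial table:
#' condition summaries, per-participant adaptation effects, the paired
#' t-test between the two standards' effects, the count of participants
#' with stronger sub-second compression, and the baseline-600 PSE-JND
#' correlation.
#'
#' @param trials A trial table.
#' @param standards The two standards, shorter first.
#' @param ... Passed to [summarize_conditions()].
#' @return A list with `summary` (the `condition_summary`), `effect_test`
#'   (t, df, p), `count_stronger` and `pse_jnd_cor`.
#' @export
analyze_trials <- function(trials, standards = c(600, 1200), ...) {
  cs <- summarize_conditions(trials, ...)
  eff <- cs$effects
  test <- paired_t_test(eff[[paste0("effect_", standards[1])]],
                        eff[[paste0("effect_", standards[2])]])
  cnt <- count_stronger_effect(eff, standards)
  base600 <- cs$fits[cs$fits$condition == "baseline" &
                       cs$fits$standard_ms == standards[1] &
                       !is.na(cs$fits$pse), ]
  r <- pearson_correlation(base600$pse, base600$jnd)
  list(summary = cs, effect_test = test, count_stronger = cnt,
       pse_jnd_cor = r)
}
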