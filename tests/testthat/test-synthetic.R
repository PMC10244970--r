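test_that("zero between-participant spread collapses everyone onto the means", {
  cells <- default_population_cells()
  cells$pse_sem <- 0
  cells$jnd_sem <- 0
  obs <- sample_population(population_spec(cells = cells), seed = 1)
  for (i in seq_len(nrow(cells))) {
    sub <- obs[obs$condition == cells$condition[i] &
                 obs$standard_ms == cells$standard_ms[i], ]
    expect_equal(sub$mu_pct, rep(cells$pse_mean[i], 20))
    expect_equal(sub$jnd_pct, rep(cells$jnd_mean[i], 20))
  }
})

test_that("population sampling is deterministic and centred on the spec means", {
  s1 <- sample_population(population_spec(), seed = 33)
  s2 <- sample_population(population_spec(), seed = 33)
  expect_identical(s1, s2)
  s3 <- sample_population(population_spec(), seed = 34)
  expect_false(identical(s1$mu_pct, s3$mu_pct))
  # sample mean of mu within 3 s.e.m. of the cell mean
  cells <- default_population_cells()
  for (i in seq_len(nrow(cells))) {
    sub <- s1[s1$condition == cells$condition[i] &
                s1$standard_ms == cells$standard_ms[i], ]
    expect_lt(abs(mean(sub$mu_pct) - cells$pse_mean[i]), 3 * cells$pse_sem[i] * sqrt(20))
  }
  expect_true(all(s1$sigma_pct > 0.5))
})

test_that("the optional baseline-600 PSE-JND coupling is injected at the requested level", {
  spec <- population_spec(n_participants = 600, baseline600_pse_jnd_cor = 0.67)
  obs <- sample_population(spec, seed = 5)
  b600 <- obs[obs$condition == "baseline" & obs$standard_ms == 600, ]
  expect_equal(stats::cor(b600$mu_pct, b600$jnd_pct), 0.67, tolerance = 0.1)
  other <- obs[obs$condition == "adaptation" & obs$standard_ms == 600, ]
  expect_lt(abs(stats::cor(other$mu_pct, other$jnd_pct)), 0.15)
})

test_that("contamination plants exactly the three documented overestimators on top", {
  obs <- sample_population(population_spec(contaminate = TRUE), seed = 12)
  b600 <- obs[obs$condition == "baseline" & obs$standard_ms == 600, ]
  expect_equal(sort(b600$mu_pct, decreasing = TRUE)[1:3],
               c(21.73, 15.73, 11.07))
  expect_lt(max(b600$mu_pct[-(1:3)]), 11.07)
})

test_that("simulated trials match the design exactly", {
  obs <- sample_population(population_spec(n_participants = 3), seed = 2)
  tr <- simulate_trials(obs, seed = 3)
  expect_equal(sort(unique(tr$comparison_pct)),
               c(-66.67, -33.33, -16.67, 0, 16.67, 33.33, 66.67))
  counts <- table(tr$participant, tr$condition, tr$standard_ms)
  expect_true(all(counts == 7 * 20))
  expect_true(all(tr$response %in% c(0, 1)))
  expect_identical(tr, simulate_trials(obs, seed = 3))
})

test_that("a noiseless observer responds as a step function", {
  obs <- data.frame(participant = "P01", condition = "baseline",
                    standard_ms = 600, mu_pct = 0, jnd_pct = 1e-6,
                    sigma_pct = 1e-6)
  tr <- simulate_trials(obs, seed = 1)
  expect_true(all(tr$response[tr$comparison_pct < 0] == 0))
  expect_true(all(tr$response[tr$comparison_pct > 0] == 1))
})

test_that("fits on simulated trials recover the generating parameters", {
  obs <- sample_population(population_spec(n_participants = 6), seed = 8)
  obs <- obs[obs$condition == "baseline" & obs$standard_ms == 600, ]
  design <- experiment_design(min_reps = 150) # large reps: small fitting noise
  tr <- simulate_trials(obs, design, seed = 9)
  for (p in obs$participant) {
    sub <- tr[tr$participant == p, ]
    fit <- fit_cumulative_gaussian(sub$comparison_pct, sub$response)
    o <- obs[obs$participant == p, ]
    # ~3x the information-bound standard error at 150 reps (se ~ 1.6)
    expect_lt(abs(fit$mu - o$mu_pct), 5)
    expect_lt(abs(stats::qnorm(0.75) * fit$sigma - o$jnd_pct), 5)
  }
})

test_that("the model-driven observer is unbiased at baseline and compressed under flicker", {
  m <- cached_model()
  tr <- simulate_model_observer(m$bank, m$filter, m$mapping,
                                design = experiment_design(min_reps = 40),
                                decision_noise_pct = 8, seed = 4)
  base600 <- tr[tr$condition == "baseline" & tr$standard_ms == 600, ]
  fb <- fit_cumulative_gaussian(base600$comparison_pct, base600$response)
  expect_lt(abs(fb$mu), 3)
  ad600 <- tr[tr$condition == "adaptation" & tr$standard_ms == 600, ]
  fa <- fit_cumulative_gaussian(ad600$comparison_pct, ad600$response)
  expect_lt(fa$mu, -3) # flicker adaptation compresses the adapted standard
})

test_that("model-observer compression is stronger at 600 than 1200 ms on average", {
  m <- cached_model()
  pses <- sapply(1:6, function(s) {
    tr <- simulate_model_observer(m$bank, m$filter, m$mapping,
                                  design = experiment_design(min_reps = 30),
                                  decision_noise_pct = 10, seed = s)
    vapply(c(600, 1200), function(std) {
      a <- tr[tr$condition == "adaptation" & tr$standard_ms == std, ]
      b <- tr[tr$condition == "baseline" & tr$standard_ms == std, ]
      fit_cumulative_gaussian(a$comparison_pct, a$response)$mu -
        fit_cumulative_gaussian(b$comparison_pct, b$response)$mu
    }, numeric(1))
  })
  expect_lt(mean(pses[1, ]), mean(pses[2, ]))
  expect_lt(mean(pses[1, ]), 0)
})
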