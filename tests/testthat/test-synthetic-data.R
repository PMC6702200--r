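# Trial-level generator: determinism, trait structure, mixture behaviour,
# monotonicity invariants and the frozen default calibration.

test_that("simulation is a pure function of the master seed", {
  cfg <- pvt_protocol(seed = 11,
                      session_times_by_day = list("4" = c(10, 20)))
  s1 <- simulate_study(4, cfg)
  s2 <- simulate_study(4, cfg)
  expect_identical(lapply(s1$sessions, `[[`, "trials"),
                   lapply(s2$sessions, `[[`, "trials"))
  expect_identical(s1$traits, s2$traits)
  cfg2 <- pvt_protocol(seed = 12,
                       session_times_by_day = list("4" = c(10, 20)))
  s3 <- simulate_study(4, cfg2)
  expect_false(identical(s1$traits, s3$traits))
  expect_false(identical(s1$sessions[[1]]$trials, s3$sessions[[1]]$trials))
})

test_that("each session has its own stream, independent of evaluation order", {
  cfg <- pvt_protocol(seed = 5, session_times_by_day = list("4" = c(10, 20)))
  study <- simulate_study(3, cfg)
  # re-simulating one participant's session in isolation reproduces the
  # study's version bit for bit
  tr <- study$traits[2, , drop = FALSE]
  alone <- simulate_session(tr, 4, 20, cfg)
  in_study <- Filter(function(s) s$participant_id == tr$participant_id &&
                       s$time_since_wake == 20, study$sessions)[[1]]
  expect_identical(alone$trials, in_study$trials)
})

test_that("trait cross-block correlation follows the configuration", {
  for (rho in c(0, 0.6)) {
    cfg <- pvt_protocol(seed = 33, trait_correlation = rho)
    co <- sample_cohort(20000, cfg)
    # base_speed is linear in the first latent score, lapse_propensity in the
    # third, so their correlation estimates the cross-block parameter
    expect_equal(cor(co$base_speed, co$lapse_propensity), rho,
                 tolerance = 0.05)
    expect_equal(cor(co$base_speed, co$base_sd), 0.3, tolerance = 0.06)
    # within-block correlation is fixed by propensity_gain_cor, not rho
    expect_equal(cor(co$lapse_propensity, co$homeo_gain), 0.2,
                 tolerance = 0.06)
  }
  expect_error(sample_cohort(1), "n must be")
})

test_that("a lapse-free attentive participant produces the plain lognormal", {
  cfg <- pvt_protocol(seed = 2, false_start_rate = 0, wrong_button_rate = 0,
                      traits = list(attentive_tot_drift = 0))
  tr <- data.frame(participant_id = "P001", base_speed = log(300),
                   base_sd = 1e-9, lapse_propensity = -50, homeo_gain = 0,
                   circ_amp = 0, circ_phase = 22, tot_gain = 0)
  counts <- vapply(1:10, function(k) {
    s <- simulate_session(tr, 4, 10, cfg, seed = 1000 + k)
    expect_true(all(abs(s$trials$rt_ms - 300) < 0.01))
    expect_true(all(s$trials$button_ok == 1))
    expect_true(all(s$trials$timeout == 0))
    nrow(s$trials)
  }, 0)
  # renewal process: about 600 s / (5 s mean ISI + 0.3 s response)
  expect_gt(mean(counts), 105)
  expect_lt(mean(counts), 121)
})

test_that("lapse-state reaction times are heavy-tailed above 500 ms", {
  cfg <- pvt_protocol(seed = 3, false_start_rate = 0, wrong_button_rate = 0)
  tr <- data.frame(participant_id = "P001", base_speed = log(300),
                   base_sd = 0.1, lapse_propensity = 8, homeo_gain = 0,
                   circ_amp = 0, circ_phase = 22, tot_gain = 0)
  rts <- unlist(lapply(1:40, function(k) {
    s <- simulate_session(tr, 2, 10, cfg, seed = 200 + k)
    s$trials$rt_ms[s$trials$timeout == 0]
  }))
  expect_true(all(rts >= 500))
  # Pareto(alpha = 2) with minimum 500: median ratio is sqrt(2)
  expect_equal(median(rts) / 500, sqrt(2), tolerance = 0.1)
})

test_that("lapse odds increase with homeostatic gain and with hours awake", {
  cfg <- pvt_protocol(seed = 4)
  base <- data.frame(participant_id = "P001", base_speed = log(290),
                     base_sd = 0.15, lapse_propensity = -2.5, homeo_gain = 0.4,
                     circ_amp = 0, circ_phase = 22, tot_gain = 0.02)
  high <- base
  high$homeo_gain <- 1.2
  lapses <- function(tr, t, k) {
    s <- simulate_session(tr, 4, t, cfg, seed = 900 + k)
    x <- s$trials
    sum(x$rt_ms[x$timeout == 0] > 500, na.rm = TRUE) + sum(x$timeout)
  }
  n_base <- sum(vapply(1:20, function(k) lapses(base, 24, k), 0))
  n_high <- sum(vapply(1:20, function(k) lapses(high, 24, k), 0))
  expect_gt(n_high, n_base)
  n_early <- sum(vapply(1:20, function(k) lapses(high, 16, k), 0))
  expect_gt(n_high, n_early)
  # deterministic counterpart on the log-odds model itself
  eta <- vapply(c(16, 18, 20, 22, 24), function(t)
    pvtvuln:::lapse_logodds(high, t, 5, cfg), 0)
  expect_true(all(diff(eta) > 0))
  expect_identical(pvtvuln:::homeo_basis(10, 3), 0)
})

test_that("baseline sessions are exchangeable when only circadian terms vary", {
  cfg <- pvt_protocol(seed = 6, false_start_rate = 0, wrong_button_rate = 0)
  tr <- data.frame(participant_id = "P001", base_speed = log(290),
                   base_sd = 0.15, lapse_propensity = -3, homeo_gain = 0.8,
                   circ_amp = 0, circ_phase = 22, tot_gain = 0.03)
  pull <- function(t, off) unlist(lapply(1:60, function(k) {
    s <- simulate_session(tr, 2, t, cfg, seed = off + k)
    s$trials$rt_ms[s$trials$timeout == 0]
  }))
  a <- pull(4, 3000)
  b <- pull(14, 7000)
  ks <- suppressWarnings(stats::ks.test(a, b))
  expect_gt(ks$p.value, 0.001)
})

test_that("representative trait profiles land in the reported lapse bands", {
  cfg <- pvt_protocol(seed = 8)
  tsd_mean <- function(group, off) {
    tr <- example_traits(group, cfg)
    mean(vapply(1:4, function(rep) {
      mean(vapply(c(16, 18, 20, 22, 24), function(t) {
        s <- simulate_session(tr, 4, t, cfg, seed = off + 10 * rep + t)
        x <- s$trials
        sum(x$rt_ms[x$timeout == 0] > 500, na.rm = TRUE) + sum(x$timeout)
      }, 0))
    }, 0))
  }
  v <- tsd_mean("vulnerable", 40000)
  r <- tsd_mean("resilient", 50000)
  expect_gte(v, 30.6)
  expect_lte(v, 52.8)
  expect_gte(r, 0)
  expect_lte(r, 13.6)
  expect_gt(v, r)
})

test_that("a default cohort reproduces the calibrated study conditions", {
  cfg <- pvt_protocol(seed = 2024)
  study <- simulate_study(160, cfg)
  scores <- tsd_scores(study)
  labels <- assign_labels(scores)
  gm <- tapply(labels$tsd_mean_lapses, labels$label, mean)
  expect_gte(gm[["resilient"]], 0)
  expect_lte(gm[["resilient"]], 13.6)
  expect_gte(gm[["intermediate"]], 14.0)
  expect_lte(gm[["intermediate"]], 30.4)
  expect_gte(gm[["vulnerable"]], 30.6)
  expect_lte(gm[["vulnerable"]], 52.8)
  # baseline lapse rate explains about half the TSD variance
  base <- tsd_scores(study, times = c(4, 6, 8, 10, 12, 14))
  r2 <- summary(lm(scores ~ base[names(scores)]))$r.squared
  expect_gt(r2, 0.35)
  expect_lt(r2, 0.65)
  # about 37% of participants average <= 2 lapses per baseline session
  hp <- select_high_performers(study)
  expect_gt(length(hp) / 160, 0.20)
  expect_lt(length(hp) / 160, 0.50)
  # trait-outcome separability: ground-truth gain ranks with the outcome
  rho <- cor(study$traits$homeo_gain, scores[study$traits$participant_id],
             method = "spearman")
  expect_gt(rho, 0.6)
})

test_that("trial CSV round trip preserves the analysis-relevant content", {
  cfg <- pvt_protocol(seed = 21,
                      session_times_by_day = list("4" = c(16, 18, 20, 22, 24)))
  study <- simulate_study(4, cfg)
  path <- tempfile(fileext = ".csv")
  write_trials_csv(study, path)
  back <- read_trials_csv(path)
  expect_s3_class(back, "pvt_study")
  expect_length(back$sessions, length(study$sessions))
  expect_equal(tsd_scores(back), tsd_scores(study))
  expect_error(read_trials_csv({
    p2 <- tempfile(fileext = ".csv")
    write.csv(data.frame(a = 1), p2, row.names = FALSE)
    p2
  }), "missing columns")
})

test_that("protocol configuration validates, prints and round-trips", {
  expect_error(pvt_protocol(isi_range = c(9, 1)), "isi_range")
  expect_error(pvt_protocol(trait_correlation = 0.99), "trait_correlation")
  expect_error(pvt_protocol(traits = list(nope = 1)), "unknown trait")
  cfg <- pvt_protocol(seed = 77, trait_correlation = 0.25,
                      traits = list(homeo_gain_mean = 0.9))
  expect_output(print(cfg), "PVT study protocol")
  expect_equal(baseline_times(cfg), seq(4, 14, 2))
  expect_equal(tsd_times(cfg), seq(16, 24, 2))
  path <- tempfile(fileext = ".json")
  write_protocol(cfg, path)
  back <- read_protocol(path)
  expect_equal(back$traits$homeo_gain_mean, 0.9)
  expect_equal(back$trait_correlation, 0.25)
  expect_equal(sample_cohort(5, back), sample_cohort(5, cfg))
})
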