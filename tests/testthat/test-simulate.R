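test_that("generation is bit-identical under a fixed seed", {
  cfg <- simulation_config(n_athletes = 40L, seed = 123L)
  c1 <- generate_cohort(cfg)
  c2 <- generate_cohort(cfg)
  expect_identical(c1$athletes, c2$athletes)
  expect_identical(c1$evals, c2$evals)
  c3 <- generate_cohort(simulation_config(n_athletes = 1L, seed = 5L))
  expect_identical(nrow(c3$athletes), 1L)
  expect_identical(c3$athletes, generate_cohort(simulation_config(
    n_athletes = 1L, seed = 5L))$athletes)
})

test_that("structural-zero probability one collapses every episode to day-0 recovery", {
  coh <- generate_cohort(simulation_config(n_athletes = 30L, zi_prob = 1,
                                           seed = 2L))
  expect_true(all(coh$evals$day_post_injury == 0L))
  expect_true(all(rowSums(coh$evals[, scat5_symptoms]) == 0L))
  rec <- time_to_recovery(coh)
  expect_true(all(rec$recovery_day == 0L))
})

test_that("config validation rejects impossible parameters", {
  expect_error(simulation_config(n_athletes = 0L), "n_athletes")
  expect_error(simulation_config(zi_prob = 1.2), "probabilities")
  expect_error(simulation_config(decay_rate = -0.1), ">= 0")
  expect_error(simulation_config(symptom_concentration = 0), "concentration")
  expect_error(simulation_config(profile_weights = c(headache = 1)), "22")
  expect_error(simulation_config(sex_symptom_logw = c(migraine = 1)), "migraine")
})

test_that("empirical sex fraction matches the configured ratio", {
  coh <- generate_cohort(simulation_config(n_athletes = 2000L, seed = 31L))
  p_hat <- mean(coh$athletes$sex == "female")
  se <- sqrt(0.5 * 0.5 / 2000)
  expect_lt(abs(p_hat - 0.5), 3 * se)
})

test_that("day-0 mean severity matches the lognormal-adjusted expectation", {
  # small random-effect SDs so the severity cap at 132 rarely binds;
  # E[day-0 total] = (1 - zi) * baseline * exp((sd_g^2 + sd_a^2) / 2)
  cfg <- simulation_config(n_athletes = 3000L, sport_group_sd = 0.1,
                           athlete_sd = 0.2, seed = 17L)
  coh <- generate_cohort(cfg)
  d0 <- coh$evals[coh$evals$day_post_injury == 0L, scat5_symptoms]
  expected <- (1 - cfg$zi_prob) * cfg$baseline_mean_severity *
    exp((cfg$sport_group_sd^2 + cfg$athlete_sd^2) / 2)
  expect_lt(abs(mean(rowSums(d0)) - expected), 1.5)
})

test_that("expected severity follows the exponential decay closed form", {
  # near-deterministic settings: no zero inflation, tight dispersion,
  # no random effects; the day-14/day-0 mean ratio is exp(-14 * decay)
  cfg <- simulation_config(n_athletes = 400L, baseline_mean_severity = 80,
                           sport_group_sd = 0, athlete_sd = 0,
                           nb_dispersion = 50, zi_prob = 0, seed = 9L)
  coh <- generate_cohort(cfg)
  sev <- rowSums(coh$evals[, scat5_symptoms])
  m0 <- mean(sev[coh$evals$day_post_injury == 0L])
  m14 <- mean(sev[coh$evals$day_post_injury == 14L])
  expect_equal(m14 / m0, exp(-0.18 * 14), tolerance = 0.15)
})

test_that("faster decay gives stochastically shorter recoveries", {
  grid <- c(0.05, 0.12, 0.25, 0.4)
  med <- vapply(grid, function(d) {
    coh <- generate_cohort(simulation_config(n_athletes = 250L, decay_rate = d,
                                             seed = 77L))
    stats::median(time_to_recovery(coh)$recovery_day, na.rm = TRUE)
  }, numeric(1))
  expect_identical(cor(grid, med, method = "spearman"), -1)
})

test_that("day-0 profile count rises with baseline severity", {
  mean_np <- vapply(c(8, 35, 90), function(b) {
    coh <- generate_cohort(simulation_config(n_athletes = 300L,
                                             baseline_mean_severity = b,
                                             seed = 44L))
    init <- initial_table(coh)
    mean(init$n_profiles)
  }, numeric(1))
  expect_true(all(diff(mean_np) > 0))
})

test_that("the generative truth record round-trips bit-exactly", {
  cfg <- simulation_config(n_athletes = 25L, seed = 99L, decay_rate = 0.21)
  coh <- generate_cohort(cfg)
  expect_identical(truth_record(coh), cfg)
  f <- withr::local_tempfile(fileext = ".json")
  write_truth_record(truth_record(coh), f)
  expect_identical(read_truth_record(f), cfg)
  expect_identical(read_truth_record(f)$seed, 99L)
  expect_error(truth_record(make_cohort(list(a1 = list(days = 0L, sev = 1L)))),
               "synthetic")
})

test_that("generated cohorts round-trip through the CSV interfaces", {
  coh <- generate_cohort(simulation_config(n_athletes = 20L, seed = 3L))
  fs <- withr::local_tempfile(fileext = ".csv")
  fm <- withr::local_tempfile(fileext = ".csv")
  write_symptom_csv(coh$evals, fs)
  write_metadata_csv(coh$athletes, fm)
  rebuilt <- src_cohort(read_metadata_csv(fm), read_symptom_csv(fs))
  expect_identical(rebuilt$evals[, scat5_symptoms],
                   coh$evals[, scat5_symptoms])
  expect_identical(rebuilt$athletes$sex, coh$athletes$sex)
})
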