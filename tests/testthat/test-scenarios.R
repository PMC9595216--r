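test_that("observation_schedule builds the named schedules", {
  mixed <- observation_schedule("mixed", 20)
  expect_equal(sum(mixed == "noxious"), 5)
  expect_equal(sum(mixed == "harmless"), 7)
  expect_equal(sum(mixed == "unobserved"), 8)
  expect_true(all(mixed[1:5] == "noxious"))
  expect_true(all(mixed[12:18] == "harmless"))
  expect_error(observation_schedule("mixed", 15), ">= 18")

  expect_equal(as.character(observation_schedule("all_harmless", 20)),
               rep("harmless", 20))
  ther <- observation_schedule("therapy", 50, 10)
  expect_equal(which(ther == "harmless"), seq(5, 50, by = 5))
  expect_error(observation_schedule("therapy", 10, 11), "between")
  expect_error(observation_schedule("sauna", 20))
})

test_that("scenario results are reproducible from their provenance", {
  a <- run_scenario("treatment_resistance", n_trials = 5, seed = 9)
  b <- run_scenario("treatment_resistance", n_trials = 5, seed = 9)
  expect_identical(a$run$trajectories, b$run$trajectories)
  expect_error(run_scenario("figment"), "unknown scenario")
  expect_error(run_scenario("mixed", observer = "nobody"), "unknown observer")
})

test_that("mixed scenario: dynamic healthy inference vs chronic flatness", {
  h <- run_scenario("mixed", "healthy", n_trials = 40, seed = 2)
  c <- run_scenario("mixed", "chronic", n_trials = 40, seed = 2)

  # trial 1: healthy q(pain) much higher under noxious (steps 1-5) than
  # under harmless input (steps 12-18); threshold 0.3 is the recorded
  # operationalization of "drastically"
  contrast <- mean(h$run$trajectories[1, 1:5]) -
    mean(h$run$trajectories[1, 12:18])
  expect_gte(contrast, 0.3)

  # chronic trajectories are flat ("hardly any deviations from the prior"):
  # per-trial range < 0.15, and strictly smaller than the healthy range in
  # every trial
  rng <- function(x) apply(x, 1, function(r) diff(range(r)))
  expect_true(all(rng(c$run$trajectories) < 0.15))
  expect_true(all(rng(c$run$trajectories) < rng(h$run$trajectories)))
})

test_that("prolonged noxious exposure raises interior q(pain) through learning", {
  for (ob in c("healthy", "chronic")) {
    r <- run_scenario("prolonged_noxious", ob, n_trials = 40, seed = 3)
    interior <- 2:19
    expect_gte(mean(r$run$trajectories[40, interior]),
               mean(r$run$trajectories[1, interior]))
  }
})

test_that("treatment resistance: final q(pain) pinned at the target marginal", {
  r <- run_scenario("treatment_resistance", n_trials = 40, seed = 5)
  expect_equal(r$run$n_steps, 20)
  expect_true(all(abs(r$run$trajectories[, 20] - 0.7) < 0.01))
  # initial priors really do vary across trials
  expect_gt(diff(range(r$run$trajectories[, 1])), 0.3)
})

test_that("therapy: accurate likelihoods beat ambiguous ones; ambiguous relapses", {
  amb <- run_scenario("therapy_ambiguous", seed = 5)
  acc <- run_scenario("therapy_accurate", seed = 5)
  expect_equal(amb$run$n_steps, 50)
  expect_lt(mean(acc$run$trajectories), mean(amb$run$trajectories))

  # ambiguous observer: before every later session the marginal has
  # returned to within 0.05 of the preset 0.7
  sessions <- seq(5, 50, by = 5)
  pre_session <- amb$run$trajectories[, sessions[-1] - 1]
  expect_true(all(abs(pre_session - 0.7) < 0.05))

  # accurate observer: harmless exposure actually lowers q(pain) at sessions
  expect_lt(min(acc$run$trajectories[, sessions]), 0.5)
})

test_that("results round-trip through CSV and JSON", {
  r <- run_scenario("mixed", "chronic", n_trials = 4, seed = 1)
  csv <- withr::local_tempfile(fileext = ".csv")
  js <- withr::local_tempfile(fileext = ".json")
  write_result(r, csv, "csv")
  write_result(r, js, "json")

  df <- read_result(csv)
  expect_equal(nrow(df), 80)
  expect_equal(names(df),
               c("scenario", "trial", "time_step", "q_pain", "free_energy"))
  expect_equal(matrix(df$q_pain, 4, 20, byrow = TRUE), r$run$trajectories,
               tolerance = 1e-15)

  back <- read_result(js)
  expect_equal(back$trajectories, unname(r$run$trajectories),
               tolerance = 1e-15)
  expect_equal(back$provenance$seed, 1)
  # provenance re-executed reproduces the trajectories
  again <- run_scenario(back$scenario, "chronic",
                        n_trials = back$provenance$n_trials,
                        seed = back$provenance$seed)
  expect_identical(again$run$trajectories, r$run$trajectories)
})

test_that("cli runs scenarios, is deterministic, and signals usage errors", {
  out1 <- withr::local_tempfile(fileext = ".csv")
  out2 <- withr::local_tempfile(fileext = ".csv")
  args <- c("mixed", "--observer", "chronic", "--trials", "4", "--seed", "7")
  expect_equal(suppressMessages(cli_main(c(args, "--out", out1))), 0L)
  expect_equal(suppressMessages(cli_main(c(args, "--out", out2))), 0L)
  df <- read_result(out1)
  expect_equal(nrow(df), 80)
  expect_identical(readLines(out1), readLines(out2))

  expect_equal(suppressMessages(cli_main(c("mixed", "--observer", "nobody",
                                           "--out", out1))), 2L)
  expect_equal(suppressMessages(cli_main(c("no_such_scenario"))), 2L)
  expect_equal(suppressMessages(cli_main(character(0))), 2L)

  # config file overrides the observer
  cfg <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(prior = list(lam = c(0.5, 0.5), nu = 10)), cfg,
                       auto_unbox = TRUE, digits = NA)
  outj <- withr::local_tempfile(fileext = ".json")
  expect_equal(suppressMessages(cli_main(c("prolonged_harmless", "--trials", "2",
                                           "--config", cfg, "--out", outj))), 0L)
  expect_equal(read_result(outj)$provenance$n_trials, 2)
})
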