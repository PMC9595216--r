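# Named, seeded reproductions of the simulation experiments: mixed
# observations, prolonged exposure, null-space treatment resistance, and
# exposure therapy under ambiguous vs. accurate likelihood models.

SCENARIO_NAMES <- c("mixed", "prolonged_noxious", "prolonged_harmless",
                    "treatment_resistance", "therapy_ambiguous",
                    "therapy_accurate")

#' Build a named observation schedule
#'
#' * `"mixed"` — noxious input at steps 1-5 and harmless input at steps
#'   12-18 (1-based, both ends inclusive), unobserved elsewhere; needs
#'   `n_steps >= 18`.
#' * `"all_noxious"` / `"all_harmless"` — homogeneous input at every step.
#' * `"therapy"` — harmless input at `therapy_sessions` evenly spaced steps
#'   (every `n_steps / therapy_sessions`-th step), unobserved elsewhere.
#'
#' @param name Schedule name.
#' @param n_steps Chain length.
#' @param therapy_sessions Number of exposure sessions (therapy only).
#' @return An [obs_schedule()].
#' @export
observation_schedule <- function(name = c("mixed", "all_noxious",
                                          "all_harmless", "therapy"),
                                 n_steps = 20, therapy_sessions = 10) {
  name <- match.arg(name)
  entries <- rep(UNOBSERVED, n_steps)
  if (name == "mixed") {
    if (n_steps < 18) stop("mixed schedule needs n_steps >= 18", call. = FALSE)
    entries[1:5] <- "noxious"
    entries[12:18] <- "harmless"
  } else if (name == "all_noxious") {
    entries[] <- "noxious"
  } else if (name == "all_harmless") {
    entries[] <- "harmless"
  } else {
    if (therapy_sessions < 1 || therapy_sessions > n_steps) {
      stop("therapy_sessions must be between 1 and n_steps", call. = FALSE)
    }
    spacing <- n_steps / therapy_sessions
    entries[round(spacing * seq_len(therapy_sessions))] <- "harmless"
  }
  obs_schedule(entries)
}

resolve_observer <- function(observer) {
  if (inherits(observer, "chain_model")) {
    return(list(model = observer, name = "custom"))
  }
  if (!is.character(observer) || !(observer %in% c("healthy", "chronic"))) {
    stop("unknown observer: ", paste(observer, collapse = ","), call. = FALSE)
  }
  list(model = preset_observer(observer), name = observer)
}

# Trials without parameter updates: propagate only.
run_static <- function(models, schedules, parameterization) {
  n_trials <- length(schedules)
  n_steps <- models[[1]]$n_steps
  trajectories <- matrix(NA_real_, n_trials, n_steps)
  free_energies <- numeric(n_trials)
  for (trial in seq_len(n_trials)) {
    sweep <- propagate(models[[trial]], schedules[[trial]], parameterization)
    trajectories[trial, ] <- sweep$singleton[, 1]
    free_energies[trial] <- sweep$free_energy
  }
  structure(list(trajectories = trajectories, free_energies = free_energies,
                 final_model = models[[n_trials]], n_trials = n_trials,
                 n_steps = n_steps, seed = NULL,
                 parameterization = parameterization),
            class = "learning_run")
}

#' Run a named simulation scenario
#'
#' * `"mixed"` — observer exposed to the mixed schedule for `n_trials`
#'   learning trials on a 20-step chain.
#' * `"prolonged_noxious"` / `"prolonged_harmless"` — homogeneous input at
#'   all 20 steps, `n_trials` learning trials.
#' * `"treatment_resistance"` — each trial draws a fresh transition table
#'   from the stationary family of `target_marginal` (second-eigenvalue
#'   magnitude capped at `max_second_eigenvalue`) and a fresh uniform-random
#'   prior q(pain), then runs exact inference on a fully unobserved 20-step
#'   chain (mean parameters, no learning): the marginal relaxes to the
#'   target regardless of the prior.
#' * `"therapy_ambiguous"` / `"therapy_accurate"` — 10 evenly spaced
#'   exposure sessions (harmless input) over 50 steps; the transition is a
#'   sampled stationary-family member for `target_marginal`, the prior sits
#'   at the target; the likelihood is the ambiguous/imprecise table
#'   (0.6/0.4 both rows, nu = 20) or the accurate/precise one
#'   (0.8/0.2, 0.1/0.9, nu = 100). Learns across trials unless
#'   `learn = FALSE`.
#'
#' @param name Scenario name.
#' @param observer `"healthy"`, `"chronic"` or a [chain_model()] (ignored by
#'   the scenarios that construct their own null-space models).
#' @param n_trials Number of learning trials (default 40).
#' @param seed Integer seed controlling every random draw in the scenario.
#' @param n_steps Chain length override; defaults to 20 (50 for therapy).
#' @param target_marginal Stationary target p(pain) for the null-space
#'   scenarios (default 0.7).
#' @param max_second_eigenvalue Eigenvalue cap for sampled transitions.
#' @param therapy_sessions Number of exposure sessions (therapy only).
#' @param learn Update parameters between trials (therapy/learning
#'   scenarios)?
#' @param parameterization `"message"` (variational default) or `"mean"`.
#' @return A `scenario_result`: fields `scenario`, `observer`, `run` (a
#'   `learning_run`) and `provenance`.
#' @export
run_scenario <- function(name, observer = "healthy", n_trials = 40, seed = 1,
                         n_steps = NULL, target_marginal = 0.7,
                         max_second_eigenvalue = 0.8, therapy_sessions = 10,
                         learn = TRUE,
                         parameterization = c("message", "mean")) {
  parameterization <- match.arg(parameterization)
  if (!(name %in% SCENARIO_NAMES)) {
    stop("unknown scenario: ", name, call. = FALSE)
  }
  if (n_trials < 1) stop("n_trials must be >= 1", call. = FALSE)
  seed <- as.integer(seed)
  set.seed(seed)
  observer_name <- if (inherits(observer, "chain_model")) "custom" else observer

  if (name %in% c("mixed", "prolonged_noxious", "prolonged_harmless")) {
    obs <- resolve_observer(observer)
    if (is.null(n_steps)) n_steps <- obs$model$n_steps
    model <- chain_model(obs$model$prior, obs$model$transition,
                         obs$model$likelihood, n_steps)
    sched_name <- switch(name, mixed = "mixed",
                         prolonged_noxious = "all_noxious",
                         prolonged_harmless = "all_harmless")
    sched <- observation_schedule(sched_name, n_steps)
    run <- if (learn) {
      run_learning(model, rep(list(sched), n_trials), seed = seed,
                   parameterization = parameterization)
    } else {
      run_static(rep(list(model), n_trials), rep(list(sched), n_trials),
                 parameterization)
    }
    observer_name <- obs$name
    schedule_desc <- sched_name
  } else if (name == "treatment_resistance") {
    if (is.null(n_steps)) n_steps <- 20
    fam <- stationary_family(target_marginal)
    lik <- cond_table(rbind(c(0.6, 0.4), c(0.6, 0.4)), nu = 20,
                      parent_labels = HIDDEN_LABELS, child_labels = OBS_LABELS)
    models <- lapply(seq_len(n_trials), function(i) {
      transition <- sample_transition(fam,
                                      max_second_eigenvalue = max_second_eigenvalue)
      q1 <- stats::runif(1)
      prior <- pc_dist(c(q1, 1 - q1), nu = 100, labels = HIDDEN_LABELS)
      chain_model(prior, transition, lik, n_steps)
    })
    sched <- obs_schedule(rep(UNOBSERVED, n_steps))
    # Exact marginal dynamics of each sampled chain: mean parameters.
    run <- run_static(models, rep(list(sched), n_trials), "mean")
    observer_name <- sprintf("null_space(pi=%g)", target_marginal)
    schedule_desc <- "all_unobserved"
  } else { # therapy_ambiguous / therapy_accurate
    if (is.null(n_steps)) n_steps <- 50
    fam <- stationary_family(target_marginal)
    transition <- sample_transition(fam,
                                    max_second_eigenvalue = max_second_eigenvalue)
    prior <- pc_dist(c(target_marginal, 1 - target_marginal), nu = 100,
                     labels = HIDDEN_LABELS)
    lik <- if (name == "therapy_ambiguous") {
      cond_table(rbind(c(0.6, 0.4), c(0.6, 0.4)), nu = 20,
                 parent_labels = HIDDEN_LABELS, child_labels = OBS_LABELS)
    } else {
      cond_table(rbind(c(0.8, 0.2), c(0.1, 0.9)), nu = 100,
                 parent_labels = HIDDEN_LABELS, child_labels = OBS_LABELS)
    }
    model <- chain_model(prior, transition, lik, n_steps)
    sched <- observation_schedule("therapy", n_steps, therapy_sessions)
    run <- if (learn) {
      run_learning(model, rep(list(sched), n_trials), seed = seed,
                   parameterization = parameterization)
    } else {
      run_static(rep(list(model), n_trials), rep(list(sched), n_trials),
                 parameterization)
    }
    observer_name <- sprintf("%s(pi=%g)", name, target_marginal)
    schedule_desc <- sprintf("therapy(%d sessions)", therapy_sessions)
  }

  structure(
    list(scenario = name, observer = observer_name, run = run,
         provenance = list(seed = seed, n_trials = n_trials,
                           n_steps = run$n_steps, schedule = schedule_desc,
                           target_marginal = target_marginal,
                           max_second_eigenvalue = max_second_eigenvalue,
                           therapy_sessions = therapy_sessions,
                           learn = learn,
                           parameterization = run$parameterization)),
    class = "scenario_result"
  )
}

#' @export
print.scenario_result <- function(x, ...) {
  cat("<scenario_result>", x$scenario, "| observer:", x$observer, "|",
      x$run$n_trials, "trials x", x$run$n_steps, "steps | seed",
      x$provenance$seed, "\n")
  invisible(x)
}

model_to_list <- function(model) {
  list(prior = list(lam = model$prior$lam, nu = model$prior$nu),
       transition = list(lam = model$transition$lam, nu = model$transition$nu),
       likelihood = list(lam = model$likelihood$lam, nu = model$likelihood$nu))
}

#' Write a scenario result to disk
#'
#' CSV is a tidy table (`scenario`, `trial`, `time_step`, `q_pain`,
#' `free_energy`) at full double precision; JSON additionally carries the
#' provenance and the final model parameters. Both round-trip through
#' [read_result()].
#'
#' @param result A `scenario_result`.
#' @param path Output file path.
#' @param format `"csv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_result <- function(result, path, format = c("csv", "json")) {
  format <- match.arg(format)
  stopifnot(inherits(result, "scenario_result"))
  ok <- tryCatch({
    if (format == "csv") {
      df <- as.data.frame(result$run)
      df <- cbind(scenario = result$scenario, df)
      df$q_pain <- sprintf("%.17g", df$q_pain)
      df$free_energy <- sprintf("%.17g", df$free_energy)
      utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
    } else {
      payload <- list(scenario = result$scenario, observer = result$observer,
                      provenance = result$provenance,
                      trajectories = result$run$trajectories,
                      free_energies = result$run$free_energies,
                      final_model = model_to_list(result$run$final_model))
      jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
    }
    TRUE
  }, error = function(e) {
    stop("failed to write ", path, ": ", conditionMessage(e), call. = FALSE)
  })
  invisible(path)
}

#' Read a written scenario result back
#'
#' @param path File written by [write_result()].
#' @param format `"csv"` or `"json"`; guessed from the extension by default.
#' @return For CSV, the tidy data frame; for JSON, a list with the
#'   trajectory matrix, free energies, provenance and final parameters.
#' @export
read_result <- function(path, format = NULL) {
  if (is.null(format)) {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  if (format == "csv") {
    utils::read.csv(path, stringsAsFactors = FALSE)
  } else {
    out <- jsonlite::fromJSON(path, simplifyVector = TRUE)
    out$trajectories <- matrix(unlist(out$trajectories),
                               nrow = length(out$free_energies), byrow = FALSE)
    out
  }
}

#' Command-line entry point
#'
#' Usage: `painhmm <scenario> [--observer healthy|chronic] [--trials N]`
#' `[--steps N] [--seed S] [--target-marginal PI] [--tolerance TOL]`
#' `[--out PATH] [--format csv|json] [--config FILE] [--log-level info|quiet]`.
#' Runs the scenario, writes the result, and logs the preset provenance.
#' A shell wrapper is installed under `inst/scripts/paincli`.
#'
#' @param args Character vector of command-line arguments (defaults to the
#'   process arguments).
#' @return Integer exit status, invisibly: 0 on success, 2 on usage errors.
#' @export
cli_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  parser <- optparse::OptionParser(
    usage = "%prog scenario [options]",
    option_list = list(
      optparse::make_option("--observer", type = "character", default = "healthy"),
      optparse::make_option("--trials", type = "integer", default = 40L),
      optparse::make_option("--steps", type = "integer", default = NA_integer_),
      optparse::make_option("--seed", type = "integer", default = 1L),
      optparse::make_option("--target-marginal", type = "double", default = 0.7,
                            dest = "target_marginal"),
      optparse::make_option("--tolerance", type = "double", default = 0.01),
      optparse::make_option("--out", type = "character", default = "result.csv"),
      optparse::make_option("--format", type = "character", default = NA_character_),
      optparse::make_option("--config", type = "character", default = NA_character_),
      optparse::make_option("--log-level", type = "character", default = "info",
                            dest = "log_level")
    )
  )
  status <- tryCatch({
    parsed <- optparse::parse_args(parser, args = args,
                                   positional_arguments = TRUE)
    opts <- parsed$options
    if (length(parsed$args) != 1L) {
      stop("exactly one scenario name is required (one of: ",
           paste(SCENARIO_NAMES, collapse = ", "), ")", call. = FALSE)
    }
    scenario <- parsed$args[[1]]
    if (!(scenario %in% SCENARIO_NAMES)) {
      stop("unknown scenario: ", scenario, call. = FALSE)
    }
    observer <- if (!is.na(opts$config)) {
      read_observer_config(opts$config)
    } else opts$observer
    fmt <- if (!is.na(opts$format)) opts$format else {
      if (grepl("\\.json$", opts$out, ignore.case = TRUE)) "json" else "csv"
    }
    if (!(fmt %in% c("csv", "json"))) stop("unknown format: ", fmt, call. = FALSE)
    result <- run_scenario(scenario, observer = observer,
                           n_trials = opts$trials, seed = opts$seed,
                           n_steps = if (is.na(opts$steps)) NULL else opts$steps,
                           target_marginal = opts$target_marginal)
    write_result(result, opts$out, fmt)
    if (identical(opts$log_level, "info")) {
      mdl <- result$run$final_model
      message(sprintf("scenario=%s observer=%s trials=%d steps=%d seed=%d",
                      result$scenario, result$observer, result$run$n_trials,
                      result$run$n_steps, opts$seed))
      message(sprintf("final prior p(pain)=%.4f (nu=%.1f); wrote %s",
                      mdl$prior$lam[1], mdl$prior$nu, opts$out))
    }
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    2L
  })
  invisible(status)
}
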