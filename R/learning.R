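# Batch free-energy learning: one sweep's posterior marginals become expected
# sufficient statistics, absorbed once per trial into the pseudocount
# parameters -- the model's analogue of overnight memory consolidation.

#' Expected sufficient-statistic counts from a posterior sweep
#'
#' Converts a [propagate()] sweep into the expected counts a batch update
#' absorbs: `prior_counts = q(H_1)` (sums to 1), `transition_counts =`
#' sum over t of the pairwise marginals (sums to N-1), and
#' `likelihood_counts` which accumulates `q(H_t)` into the observed symbol's
#' column for observed nodes only (unobserved nodes contribute nothing).
#'
#' @param sweep A `posterior_sweep`.
#' @param obs The schedule the sweep was produced for.
#' @param model The [chain_model()] supplying the alphabets.
#' @return A `count_set` with fields `prior_counts`, `transition_counts`,
#'   `likelihood_counts`.
#' @export
expected_counts <- function(sweep, obs, model) {
  stopifnot(inherits(sweep, "posterior_sweep"))
  obs <- obs_schedule(obs, model)
  N <- model$n_steps
  if (nrow(sweep$singleton) != N) {
    stop("sweep length does not match the schedule", call. = FALSE)
  }
  K <- length(model$hidden_labels)
  S <- length(model$obs_labels)

  prior_counts <- stats::setNames(sweep$singleton[1, ], model$hidden_labels)
  transition_counts <- matrix(0, K, K,
                              dimnames = list(model$hidden_labels,
                                              model$hidden_labels))
  if (N > 1) {
    for (t in seq_len(N - 1)) {
      transition_counts <- transition_counts + sweep$pairwise[t, , ]
    }
  }
  likelihood_counts <- matrix(0, K, S,
                              dimnames = list(model$hidden_labels,
                                              model$obs_labels))
  for (t in seq_len(N)) {
    s <- obs[[t]]
    if (s != UNOBSERVED) {
      j <- match(s, model$obs_labels)
      likelihood_counts[, j] <- likelihood_counts[, j] + sweep$singleton[t, ]
    }
  }
  structure(list(prior_counts = prior_counts,
                 transition_counts = transition_counts,
                 likelihood_counts = likelihood_counts),
            class = "count_set")
}

#' Hard counts from a fully observed (hidden + emission) sequence
#'
#' Complete-data sufficient statistics for parameter recovery from the
#' generative sampler: indicator counts for the first hidden state,
#' consecutive hidden pairs, and (hidden, observation) pairs.
#'
#' @param hidden Character vector of hidden states.
#' @param obs Character vector of observations, same length.
#' @param model The [chain_model()] supplying the alphabets.
#' @return A `count_set`.
#' @export
complete_data_counts <- function(hidden, obs, model) {
  stopifnot(length(hidden) == length(obs))
  h <- match(hidden, model$hidden_labels)
  o <- match(obs, model$obs_labels)
  if (anyNA(h) || anyNA(o)) stop("labels outside the model alphabets", call. = FALSE)
  K <- length(model$hidden_labels)
  S <- length(model$obs_labels)
  N <- length(h)
  prior_counts <- stats::setNames(as.numeric(seq_len(K) == h[1]),
                                  model$hidden_labels)
  transition_counts <- matrix(0, K, K,
                              dimnames = list(model$hidden_labels,
                                              model$hidden_labels))
  if (N > 1) {
    for (t in seq_len(N - 1)) {
      transition_counts[h[t], h[t + 1]] <- transition_counts[h[t], h[t + 1]] + 1
    }
  }
  likelihood_counts <- matrix(0, K, S,
                              dimnames = list(model$hidden_labels,
                                              model$obs_labels))
  for (t in seq_len(N)) {
    likelihood_counts[h[t], o[t]] <- likelihood_counts[h[t], o[t]] + 1
  }
  structure(list(prior_counts = prior_counts,
                 transition_counts = transition_counts,
                 likelihood_counts = likelihood_counts),
            class = "count_set")
}

#' Absorb a count set into a model (one batch update)
#'
#' Returns a new model whose prior, transition rows and likelihood rows have
#' absorbed the corresponding counts via [absorb_counts()]. The prior's
#' pseudocount grows by exactly 1 per sweep (one first-node datum).
#'
#' @param model A [chain_model()].
#' @param counts A `count_set` from [expected_counts()] or
#'   [complete_data_counts()].
#' @return The updated [chain_model()]; the input is unchanged.
#' @export
batch_update <- function(model, counts) {
  stopifnot(inherits(model, "chain_model"), inherits(counts, "count_set"))
  h <- model$hidden_labels
  if (!identical(names(counts$prior_counts), h) ||
      !identical(rownames(counts$transition_counts), h) ||
      !identical(rownames(counts$likelihood_counts), h) ||
      !identical(colnames(counts$likelihood_counts), model$obs_labels)) {
    stop("count alphabets do not match the model", call. = FALSE)
  }
  prior <- absorb_counts(model$prior, counts$prior_counts)
  absorb_table <- function(tab, cnt) {
    lam <- tab$lam
    nu <- tab$nu
    for (i in seq_len(nrow(lam))) {
      row <- absorb_counts(table_row(tab, i), cnt[i, ])
      lam[i, ] <- row$lam
      nu[i] <- row$nu
    }
    cond_table(lam, nu, parent_labels = tab$parent_labels,
               child_labels = tab$child_labels)
  }
  transition <- absorb_table(model$transition, counts$transition_counts)
  likelihood <- absorb_table(model$likelihood, counts$likelihood_counts)
  chain_model(prior, transition, likelihood, model$n_steps)
}

#' Run batch learning over a sequence of trials
#'
#' For each trial in order: infer with [propagate()], record the q(pain)
#' trajectory and the sweep's free energy, convert the sweep to expected
#' counts and absorb them with [batch_update()]. Deterministic given its
#' inputs; `seed` is recorded provenance for schedule generators.
#'
#' @param model Starting [chain_model()].
#' @param schedules List of [obs_schedule()]s, one per trial (a single
#'   schedule is recycled is not supported: pass `rep(list(s), n)`).
#' @param seed Optional integer recorded in the result.
#' @param parameterization Passed to [propagate()]; default `"message"`,
#'   the variational learning regime.
#' @return A `learning_run`: `trajectories` (n_trials x n_steps matrix of
#'   q(pain)), `free_energies`, `final_model`, `n_trials`, `n_steps`, `seed`.
#' @export
run_learning <- function(model, schedules, seed = NULL,
                         parameterization = c("message", "mean")) {
  parameterization <- match.arg(parameterization)
  if (length(schedules) < 1) stop("empty schedule list", call. = FALSE)
  n_trials <- length(schedules)
  trajectories <- matrix(NA_real_, n_trials, model$n_steps)
  free_energies <- numeric(n_trials)
  pain <- match("pain", model$hidden_labels)
  if (is.na(pain)) pain <- 1L
  for (trial in seq_len(n_trials)) {
    obs <- obs_schedule(schedules[[trial]], model)
    sweep <- propagate(model, obs, parameterization)
    trajectories[trial, ] <- sweep$singleton[, pain]
    free_energies[trial] <- sweep$free_energy
    model <- batch_update(model, expected_counts(sweep, obs, model))
  }
  structure(list(trajectories = trajectories,
                 free_energies = free_energies,
                 final_model = model,
                 n_trials = n_trials, n_steps = model$n_steps,
                 seed = seed, parameterization = parameterization),
            class = "learning_run")
}

#' @export
print.learning_run <- function(x, ...) {
  cat("<learning_run>", x$n_trials, "trials x", x$n_steps, "steps;",
      x$parameterization, "parameterization\n")
  invisible(x)
}

#' Tidy data frame of a learning run
#'
#' @param x A `learning_run`.
#' @param ... Unused.
#' @return Data frame with columns `trial`, `time_step`, `q_pain`,
#'   `free_energy` (the trial's free energy, repeated across its steps).
#' @export
as.data.frame.learning_run <- function(x, ...) {
  data.frame(
    trial = rep(seq_len(x$n_trials), each = x$n_steps),
    time_step = rep(seq_len(x$n_steps), times = x$n_trials),
    q_pain = as.vector(t(x$trajectories)),
    free_energy = rep(x$free_energies, each = x$n_steps)
  )
}
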