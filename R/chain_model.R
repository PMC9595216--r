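# The N-step hidden Markov model of pain perception, the healthy / chronic
# observer presets, and a seeded generative sampler.
#
# Coordinate convention used throughout: hidden index 1 = "pain",
# observation index 1 = "noxious". Time indexing is 1-based.

HIDDEN_LABELS <- c("pain", "pain_free")
OBS_LABELS <- c("noxious", "harmless")
UNOBSERVED <- "unobserved"

#' Build an N-step hidden Markov model of pain inference
#'
#' Hidden nodes H_1..H_N over \{pain, pain_free\} form a Markov chain; each
#' emits an observation over \{noxious, harmless\} (which may remain
#' unobserved). Construction only validates; no inference is performed.
#'
#' @param prior [pc_dist()] over the hidden labels (belief about H_1).
#' @param transition [cond_table()] p(H_t | H_t-1), hidden x hidden.
#' @param likelihood [cond_table()] p(S_t | H_t), hidden x observation.
#' @param n_steps Number of time steps N >= 1.
#' @return An object of class `chain_model`.
#' @export
chain_model <- function(prior, transition, likelihood, n_steps) {
  n_steps <- as.integer(n_steps)
  if (length(n_steps) != 1L || is.na(n_steps) || n_steps < 1L) {
    stop("n_steps must be a positive integer", call. = FALSE)
  }
  validate_pc_dist(prior)
  validate_cond_table(transition)
  validate_cond_table(likelihood)
  h <- prior$labels
  if (!identical(transition$parent_labels, h) ||
      !identical(transition$child_labels, h)) {
    stop("transition alphabets must match the hidden labels", call. = FALSE)
  }
  if (!identical(likelihood$parent_labels, h)) {
    stop("likelihood parent alphabet must match the hidden labels",
         call. = FALSE)
  }
  structure(
    list(n_steps = n_steps,
         hidden_labels = h,
         obs_labels = likelihood$child_labels,
         prior = prior, transition = transition, likelihood = likelihood),
    class = "chain_model"
  )
}

#' @export
print.chain_model <- function(x, ...) {
  cat("<chain_model>", x$n_steps, "steps; hidden:",
      paste(x$hidden_labels, collapse = "/"), "obs:",
      paste(x$obs_labels, collapse = "/"), "\n")
  cat("prior:\n"); print(x$prior)
  cat("transition:\n"); print(x$transition)
  cat("likelihood:\n"); print(x$likelihood)
  invisible(x)
}

#' Named observer presets
#'
#' Returns the 20-step model for one of the two published observer types.
#'
#' The healthy observer has a low, precise prior expectation of pain
#' (p(pain) = 0.2, nu = 100), an accurate, precise likelihood
#' (p(noxious|pain) = 0.8, p(noxious|pain_free) = 0.1, nu = 100) and
#' transitions favouring recovery (p(pain_free|pain) = 0.7). The chronic
#' observer has a high prior (p(pain) = 0.9, nu = 100), an ambiguous,
#' imprecise likelihood (both rows 0.6/0.4, nu = 20) and transitions biased
#' towards pain (p(pain|pain_free) = 0.7).
#'
#' Each preset's remaining transition entry is completed so that the prior
#' is the stationary distribution of the transition means (expectations are
#' stable in time): healthy p(pain|pain_free) = 0.175, chronic
#' p(pain|pain) = 0.83/0.9. Transition rows carry nu = 100; only the chronic
#' likelihood is imprecise (nu = 20).
#'
#' @param name `"healthy"` or `"chronic"`.
#' @param n_steps Chain length; default 20.
#' @return A [chain_model()].
#' @export
preset_observer <- function(name = c("healthy", "chronic"), n_steps = 20) {
  name <- match.arg(name)
  if (name == "healthy") {
    prior <- pc_dist(c(0.2, 0.8), nu = 100, labels = HIDDEN_LABELS)
    transition <- cond_table(
      rbind(c(0.3, 0.7), c(0.175, 0.825)), nu = 100,
      parent_labels = HIDDEN_LABELS, child_labels = HIDDEN_LABELS)
    likelihood <- cond_table(
      rbind(c(0.8, 0.2), c(0.1, 0.9)), nu = 100,
      parent_labels = HIDDEN_LABELS, child_labels = OBS_LABELS)
  } else {
    prior <- pc_dist(c(0.9, 0.1), nu = 100, labels = HIDDEN_LABELS)
    a <- 0.83 / 0.9  # stationarity of p(pain)=0.9 given p(pain|pain_free)=0.7
    transition <- cond_table(
      rbind(c(a, 1 - a), c(0.7, 0.3)), nu = 100,
      parent_labels = HIDDEN_LABELS, child_labels = HIDDEN_LABELS)
    likelihood <- cond_table(
      rbind(c(0.6, 0.4), c(0.6, 0.4)), nu = 20,
      parent_labels = HIDDEN_LABELS, child_labels = OBS_LABELS)
  }
  chain_model(prior, transition, likelihood, n_steps = n_steps)
}

#' Read an observer from a plain-text (JSON) config
#'
#' The config mirrors the model structure: top-level keys `prior`,
#' `transition`, `likelihood`, each with `lam` (vector or row-major matrix)
#' and `nu` (scalar or per-row), plus optional `n_steps`. Omitted components
#' fall back to the `base` preset.
#'
#' @param path Path to a JSON file.
#' @param base Preset supplying defaults for omitted components.
#' @return A [chain_model()].
#' @export
read_observer_config <- function(path, base = "healthy") {
  cfg <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  mdl <- preset_observer(base)
  n_steps <- if (!is.null(cfg$n_steps)) cfg$n_steps else mdl$n_steps
  prior <- if (!is.null(cfg$prior)) {
    pc_dist(cfg$prior$lam, cfg$prior$nu, labels = HIDDEN_LABELS)
  } else mdl$prior
  transition <- if (!is.null(cfg$transition)) {
    cond_table(matrix(unlist(cfg$transition$lam), nrow = 2, byrow = !is.matrix(cfg$transition$lam)),
               cfg$transition$nu,
               parent_labels = HIDDEN_LABELS, child_labels = HIDDEN_LABELS)
  } else mdl$transition
  likelihood <- if (!is.null(cfg$likelihood)) {
    cond_table(matrix(unlist(cfg$likelihood$lam), nrow = 2, byrow = !is.matrix(cfg$likelihood$lam)),
               cfg$likelihood$nu,
               parent_labels = HIDDEN_LABELS, child_labels = OBS_LABELS)
  } else mdl$likelihood
  chain_model(prior, transition, likelihood, n_steps = n_steps)
}

#' Observation schedule
#'
#' A per-time-step sensory schedule: each entry is `"noxious"`, `"harmless"`
#' or `"unobserved"`. Validated against a model's length and observation
#' alphabet.
#'
#' @param entries Character vector of length `n_steps`.
#' @param model Optional [chain_model()] to validate against.
#' @return Character vector of class `obs_schedule`.
#' @export
obs_schedule <- function(entries, model = NULL) {
  entries <- as.character(entries)
  allowed <- c(if (!is.null(model)) model$obs_labels else OBS_LABELS, UNOBSERVED)
  bad <- setdiff(unique(entries), allowed)
  if (length(bad) > 0) {
    stop("unknown schedule entries: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  if (!is.null(model) && length(entries) != model$n_steps) {
    stop("schedule length ", length(entries), " does not match n_steps ",
         model$n_steps, call. = FALSE)
  }
  structure(entries, class = "obs_schedule")
}

#' Sample hidden paths and observations from a model
#'
#' Draws hidden paths from the prior / transition means and observations from
#' the likelihood means. Used to generate fixtures for parameter-recovery
#' tests; reproducible for a fixed seed.
#'
#' @param model A [chain_model()].
#' @param seed Integer seed.
#' @param n_sequences Number of sequences to draw (>= 1).
#' @return List of `n_sequences` lists with character vectors `hidden` and
#'   `obs`, each of length `n_steps`.
#' @export
sample_generative <- function(model, seed, n_sequences = 1) {
  stopifnot(inherits(model, "chain_model"), n_sequences >= 1)
  set.seed(as.integer(seed))
  K <- length(model$hidden_labels)
  p0 <- mean_probabilities(model$prior)
  Tm <- param_mat(model$transition, "mean")
  L <- param_mat(model$likelihood, "mean")
  lapply(seq_len(n_sequences), function(s) {
    h <- integer(model$n_steps)
    h[1] <- sample.int(K, 1, prob = p0)
    for (t in seq_len(model$n_steps - 1L)) {
      h[t + 1L] <- sample.int(K, 1, prob = Tm[h[t], ])
    }
    o <- vapply(h, function(i) sample.int(ncol(L), 1, prob = L[i, ]), integer(1))
    list(hidden = model$hidden_labels[h], obs = model$obs_labels[o])
  })
}
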