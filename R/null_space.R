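# Stationary (null-space) family of transition tables for a target pain
# marginal. For a 2-state chain with a = p(pain|pain) and
# b = p(pain|pain_free), stationarity of pi = p(pain) reads
# pi = pi*a + (1-pi)*b, i.e. b(a) = pi*(1-a)/(1-pi): a one-parameter line,
# the null space of the stationarity constraint. The second eigenvalue of
# any member is a - b(a) = (a - pi)/(1 - pi), the per-step contraction rate
# of deviations from pi on an unobserved chain.

#' One-dimensional family of transition tables stationary for a pain marginal
#'
#' For target marginal `pi = p(pain)` in (0, 1), returns the family of
#' two-state transition tables whose stationary distribution is
#' `(pi, 1 - pi)`, parameterized by the self-transition
#' `a = p(pain | pain)`: the partner entry is
#' `b(a) = p(pain | pain_free) = pi (1 - a) / (1 - pi)`. The admissible
#' interval for `a` keeps `b` in `[0, 1]`: lower bound
#' `max(0, (2 pi - 1) / pi)`, upper bound 1.
#'
#' @param target_marginal Target p(pain), strictly inside (0, 1).
#' @return A `stationary_family` with fields `target_marginal`,
#'   `valid_interval` (length-2 vector), and functions `b(a)` (slope map)
#'   and `second_eigenvalue(a)`.
#' @export
stationary_family <- function(target_marginal) {
  pi <- as.numeric(target_marginal)
  if (length(pi) != 1L || !is.finite(pi) || pi <= 0 || pi >= 1) {
    stop("target_marginal must lie strictly inside (0, 1)", call. = FALSE)
  }
  lower <- max(0, (2 * pi - 1) / pi)
  structure(
    list(target_marginal = pi,
         valid_interval = c(lower, 1),
         b = function(a) pi * (1 - a) / (1 - pi),
         second_eigenvalue = function(a) (a - pi) / (1 - pi)),
    class = "stationary_family"
  )
}

#' @export
print.stationary_family <- function(x, ...) {
  cat("<stationary_family> p(pain) =", format(x$target_marginal),
      "; a in [", format(x$valid_interval[1]), ",",
      format(x$valid_interval[2]), "]\n")
  invisible(x)
}

#' Membership test for the stationary family
#'
#' @param family A [stationary_family()].
#' @param a Candidate self-transition p(pain | pain).
#' @return Logical: is `a` admissible (i.e. `b(a)` in `[0, 1]`)?
#' @export
family_contains <- function(family, a) {
  a >= family$valid_interval[1] - 1e-15 & a <= family$valid_interval[2] + 1e-15
}

#' Build the family member with a given self-transition
#'
#' @param family A [stationary_family()].
#' @param a Admissible self-transition p(pain | pain).
#' @param nu Row pseudocount for the returned table (default 100).
#' @return A [cond_table()] over the hidden labels.
#' @export
family_member <- function(family, a, nu = 100) {
  if (!family_contains(family, a)) {
    stop("a = ", a, " is outside the admissible interval", call. = FALSE)
  }
  b <- family$b(a)
  cond_table(rbind(c(a, 1 - a), c(b, 1 - b)), nu = nu,
             parent_labels = HIDDEN_LABELS, child_labels = HIDDEN_LABELS)
}

#' Sample a transition table from the stationary family
#'
#' Draws the self-transition `a` uniformly from the sub-interval of the
#' admissible interval where the second-eigenvalue magnitude
#' `|a - b(a)| = |a - pi| / (1 - pi)` is at most `max_second_eigenvalue`.
#' The eigenvalue cap excludes the degenerate identity endpoint `a = 1`,
#' which never relaxes towards the target.
#'
#' @param family A [stationary_family()].
#' @param seed Optional integer seed (omit to use the current RNG stream).
#' @param max_second_eigenvalue Cap on `|a - b(a)|`, in `[0, 1)`.
#' @param nu Row pseudocount of the returned table.
#' @return A [cond_table()] whose stationarity residual is below 1e-12.
#' @export
sample_transition <- function(family, seed = NULL, max_second_eigenvalue = 0.8,
                              nu = 100) {
  s <- max_second_eigenvalue
  if (s < 0 || s >= 1) stop("max_second_eigenvalue must be in [0, 1)", call. = FALSE)
  pi <- family$target_marginal
  lo <- max(family$valid_interval[1], pi - s * (1 - pi))
  hi <- min(family$valid_interval[2], pi + s * (1 - pi))
  if (lo > hi) stop("empty admissible sub-interval", call. = FALSE)
  if (!is.null(seed)) set.seed(as.integer(seed))
  a <- stats::runif(1, lo, hi)
  family_member(family, a, nu = nu)
}

#' Stationarity residual of a transition table
#'
#' Max-norm residual `||pi T - pi||_inf` of a marginal under the transition
#' means; 0 iff the marginal is stationary.
#'
#' @param transition A two-state [cond_table()].
#' @param marginal Probability vector (pain, pain_free) or scalar p(pain).
#' @return Non-negative scalar.
#' @export
stationarity_residual <- function(transition, marginal) {
  if (length(marginal) == 1) marginal <- c(marginal, 1 - marginal)
  Tm <- param_mat(transition, "mean")
  max(abs(as.numeric(marginal %*% Tm) - marginal))
}

#' Steps until an unobserved chain reaches a target pain marginal
#'
#' Propagates an unobserved chain (exact sum-product, mean parameters)
#' starting from `initial_prior` and returns the smallest number of
#' transition steps after which `|q(pain) - target| < tolerance`, or `NA`
#' if the chain never gets that close within `max_steps` transitions. With
#' no observations the deviation from a stationary target contracts by the
#' factor `|a - b|` (the second eigenvalue) each step.
#'
#' @param transition A two-state [cond_table()].
#' @param initial_prior Probability vector (pain, pain_free) or scalar
#'   q(pain) for the first node.
#' @param target Target p(pain).
#' @param tolerance Positive convergence tolerance.
#' @param max_steps Chain length budget (number of transitions examined).
#' @return Non-negative integer count of steps, or `NA_integer_`.
#' @export
convergence_time <- function(transition, initial_prior, target, tolerance,
                             max_steps = 20) {
  stopifnot(tolerance > 0)
  if (length(initial_prior) == 1) initial_prior <- c(initial_prior, 1 - initial_prior)
  prior <- pc_dist(initial_prior, nu = 100, labels = HIDDEN_LABELS)
  lik <- cond_table(rbind(c(0.5, 0.5), c(0.5, 0.5)), nu = 100,
                    parent_labels = HIDDEN_LABELS, child_labels = OBS_LABELS)
  model <- chain_model(prior, transition, lik, n_steps = max_steps + 1L)
  sweep <- propagate(model, rep(UNOBSERVED, max_steps + 1L), "mean")
  hit <- which(abs(sweep$singleton[, 1] - target) < tolerance)
  if (length(hit) == 0) return(NA_integer_)
  as.integer(hit[1] - 1L)
}
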