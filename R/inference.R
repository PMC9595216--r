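# Exact sum-product inference on the chain.
#
# Forward-backward with per-step normalization; unobserved nodes contribute
# an all-ones evidence message (equivalent to a missing factor on a chain).
# The accumulated log-normalizers give -log(evidence), which equals the
# variational free energy because inference on a tree is exact.

new_posterior_sweep <- function(singleton, pairwise, free_energy,
                                parameterization) {
  structure(
    list(singleton = singleton, pairwise = pairwise,
         free_energy = free_energy, parameterization = parameterization),
    class = "posterior_sweep"
  )
}

#' @export
print.posterior_sweep <- function(x, ...) {
  cat("<posterior_sweep>", nrow(x$singleton), "steps;",
      x$parameterization, "parameterization; free energy",
      format(x$free_energy), "\n")
  invisible(x)
}

# Evidence message for each node: likelihood column for the observed symbol,
# all-ones when unobserved.
evidence_messages <- function(model, obs, L) {
  K <- length(model$hidden_labels)
  vapply(seq_len(model$n_steps), function(t) {
    s <- obs[[t]]
    if (s == UNOBSERVED) rep(1, K) else L[, match(s, model$obs_labels)]
  }, numeric(K))  # K x N
}

impossible_evidence <- function(t) {
  stop(structure(
    class = c("painhmm_impossible_evidence", "error", "condition"),
    list(message = paste0("impossible evidence: all-zero message at step ", t),
         call = NULL)
  ))
}

#' Exact sum-product posterior on the chain
#'
#' Runs one forward and one backward message pass (the chain is singly
#' connected, so this is exact) and returns per-step singleton marginals
#' q(H_t), adjacent pairwise marginals q(H_t, H_t+1) and the sweep's free
#' energy, -log(evidence) under the chosen parameterization.
#'
#' With `parameterization = "mean"` the factors are the mean probabilities
#' and the free energy is exactly -log p(observations). With `"message"`
#' (variational default for learning) factors are the geometric-mean weights
#' `exp(E[log theta])` of the Dirichlet beliefs.
#'
#' @param model A [chain_model()].
#' @param obs An [obs_schedule()] (or character vector) of length `n_steps`.
#' @param parameterization `"mean"` or `"message"`.
#' @return A `posterior_sweep`: `singleton` (N x K matrix), `pairwise`
#'   ((N-1) x K x K array, `NULL` when N = 1), `free_energy`.
#' @export
propagate <- function(model, obs, parameterization = c("mean", "message")) {
  parameterization <- match.arg(parameterization)
  obs <- obs_schedule(obs, model)
  N <- model$n_steps
  K <- length(model$hidden_labels)

  p0 <- param_vec(model$prior, parameterization)
  Tm <- param_mat(model$transition, parameterization)
  L <- param_mat(model$likelihood, parameterization)
  e <- evidence_messages(model, obs, L)

  # forward (scaled)
  fwd <- matrix(0, N, K)
  logz <- 0
  a <- p0 * e[, 1]
  z <- sum(a)
  if (z <= 0) impossible_evidence(1)
  fwd[1, ] <- a / z
  logz <- logz + log(z)
  if (N > 1) {
    for (t in 2:N) {
      a <- as.numeric(fwd[t - 1, ] %*% Tm) * e[, t]
      z <- sum(a)
      if (z <= 0) impossible_evidence(t)
      fwd[t, ] <- a / z
      logz <- logz + log(z)
    }
  }

  # backward (scaled; scaling cancels in the normalized marginals)
  bwd <- matrix(0, N, K)
  bwd[N, ] <- 1
  if (N > 1) {
    for (t in (N - 1):1) {
      b <- as.numeric(Tm %*% (e[, t + 1] * bwd[t + 1, ]))
      zb <- sum(b)
      if (zb <= 0) impossible_evidence(t)
      bwd[t, ] <- b / zb
    }
  }

  singleton <- fwd * bwd
  singleton <- singleton / rowSums(singleton)
  dimnames(singleton) <- list(NULL, model$hidden_labels)

  pairwise <- NULL
  if (N > 1) {
    pairwise <- array(0, dim = c(N - 1, K, K),
                      dimnames = list(NULL, model$hidden_labels,
                                      model$hidden_labels))
    for (t in seq_len(N - 1)) {
      pw <- (fwd[t, ] %o% (e[, t + 1] * bwd[t + 1, ])) * Tm
      pairwise[t, , ] <- pw / sum(pw)
    }
  }

  new_posterior_sweep(singleton, pairwise, free_energy = -logz,
                      parameterization = parameterization)
}

#' Brute-force posterior by path enumeration (oracle)
#'
#' Enumerates all K^N hidden paths, computes unnormalized joint weights,
#' normalizes and marginalizes. Exponential in N; guarded at N <= 16. Kept
#' as an independent check on [propagate()].
#'
#' @inheritParams propagate
#' @return A `posterior_sweep` with the same contracts as [propagate()].
#' @export
brute_force_posterior <- function(model, obs,
                                  parameterization = c("mean", "message")) {
  parameterization <- match.arg(parameterization)
  obs <- obs_schedule(obs, model)
  N <- model$n_steps
  if (N > 16) stop("brute force guarded at N <= 16", call. = FALSE)
  K <- length(model$hidden_labels)

  p0 <- param_vec(model$prior, parameterization)
  Tm <- param_mat(model$transition, parameterization)
  L <- param_mat(model$likelihood, parameterization)
  e <- evidence_messages(model, obs, L)

  paths <- as.matrix(expand.grid(rep(list(seq_len(K)), N)))
  w <- p0[paths[, 1]] * e[, 1][paths[, 1]]
  if (N > 1) {
    for (t in 2:N) {
      w <- w * Tm[cbind(paths[, t - 1], paths[, t])] * e[, t][paths[, t]]
    }
  }
  z <- sum(w)
  if (z <= 0) impossible_evidence(NA)
  w <- w / z

  singleton <- matrix(0, N, K, dimnames = list(NULL, model$hidden_labels))
  for (t in seq_len(N)) {
    singleton[t, ] <- vapply(seq_len(K),
                             function(i) sum(w[paths[, t] == i]), numeric(1))
  }
  pairwise <- NULL
  if (N > 1) {
    pairwise <- array(0, dim = c(N - 1, K, K),
                      dimnames = list(NULL, model$hidden_labels,
                                      model$hidden_labels))
    for (t in seq_len(N - 1)) {
      for (i in seq_len(K)) for (j in seq_len(K)) {
        pairwise[t, i, j] <- sum(w[paths[, t] == i & paths[, t + 1] == j])
      }
    }
  }
  new_posterior_sweep(singleton, pairwise, free_energy = -log(z),
                      parameterization = parameterization)
}

xlogy <- function(x, y) ifelse(x == 0, 0, x * log(y))

#' Variational free energy of a sweep
#'
#' Evaluates F = E_q[log q - log p~] from the sweep's marginals using the
#' Bethe decomposition on the chain (energy minus Bethe entropy, with
#' endpoint counting numbers zero). For exact sum-product this equals the
#' `free_energy` stored by [propagate()] (-log evidence); the two routes are
#' independent, which makes the identity a useful internal check.
#'
#' @param model A [chain_model()].
#' @param obs The schedule the sweep was produced for.
#' @param sweep A `posterior_sweep` from [propagate()] or
#'   [brute_force_posterior()].
#' @return Scalar free energy.
#' @export
free_energy <- function(model, obs, sweep) {
  stopifnot(inherits(sweep, "posterior_sweep"))
  obs <- obs_schedule(obs, model)
  N <- model$n_steps
  parameterization <- sweep$parameterization

  p0 <- param_vec(model$prior, parameterization)
  Tm <- param_mat(model$transition, parameterization)
  L <- param_mat(model$likelihood, parameterization)

  q <- sweep$singleton
  energy <- -sum(xlogy(q[1, ], p0))
  for (t in seq_len(N)) {
    s <- obs[[t]]
    if (s != UNOBSERVED) {
      energy <- energy - sum(xlogy(q[t, ], L[, match(s, model$obs_labels)]))
    }
  }
  entropy <- 0
  if (N > 1) {
    for (t in seq_len(N - 1)) {
      pw <- sweep$pairwise[t, , ]
      energy <- energy - sum(xlogy(pw, Tm))
      entropy <- entropy - sum(xlogy(pw, pw))
    }
  }
  # Bethe counting: node t appears in d_t pairwise terms; subtract
  # (d_t - 1) * H(q_t). Endpoints have d = 1 (d = 0 when N = 1).
  d <- if (N == 1) 0 else c(1, rep(2, max(0, N - 2)), 1)
  for (t in seq_len(N)) {
    entropy <- entropy + (d[t] - 1) * sum(xlogy(q[t, ], q[t, ]))
  }
  energy - entropy
}
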