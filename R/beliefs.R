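# Categorical beliefs with Dirichlet pseudocounts.
#
# A belief over K categories is stored as (lam, nu): lam is the probability
# vector (the sufficient statistics of the categorical family) and nu > 0 is
# the pseudocount, interpreted as the number of data points the belief is
# based on. The effective Dirichlet counts are alpha_k = nu * lam_k.

SUM_TOL <- 1e-12

#' Categorical belief with pseudocounts
#'
#' Construct a categorical distribution parameterized by its sufficient
#' statistics `lam` (a probability vector) and a precision `nu` (a positive
#' pseudocount counting the data points the belief rests on). The implied
#' Dirichlet counts are `alpha = nu * lam`.
#'
#' @param lam Numeric probability vector of length K >= 2 (non-negative,
#'   summing to 1 within 1e-12).
#' @param nu Positive scalar pseudocount.
#' @param labels Character vector of category names; defaults to
#'   `names(lam)` or `"k1".."kK"`.
#' @return An object of class `pc_dist` with fields `labels`, `lam`, `nu`.
#' @examples
#' d <- pc_dist(c(pain = 0.2, pain_free = 0.8), nu = 100)
#' mean_probabilities(d)
#' @export
pc_dist <- function(lam, nu, labels = NULL) {
  if (is.null(labels)) {
    labels <- names(lam)
    if (is.null(labels)) labels <- paste0("k", seq_along(lam))
  }
  lam <- as.numeric(lam)
  obj <- structure(
    list(labels = as.character(labels), lam = lam, nu = as.numeric(nu)),
    class = "pc_dist"
  )
  validate_pc_dist(obj)
  obj
}

validate_pc_dist <- function(x) {
  stopifnot(inherits(x, "pc_dist"))
  k <- length(x$lam)
  if (k < 2) stop("pc_dist needs at least 2 categories", call. = FALSE)
  if (length(x$labels) != k) stop("labels/lam length mismatch", call. = FALSE)
  if (any(x$lam < 0)) stop("lam entries must be >= 0", call. = FALSE)
  if (abs(sum(x$lam) - 1) > SUM_TOL) {
    stop("lam must sum to 1 within 1e-12", call. = FALSE)
  }
  if (!is.finite(x$nu) || length(x$nu) != 1L || x$nu <= 0) {
    stop("nu must be a positive scalar", call. = FALSE)
  }
  invisible(x)
}

#' Effective Dirichlet counts of a belief
#'
#' @param dist A [pc_dist()].
#' @return Numeric vector `alpha = nu * lam`.
#' @export
effective_counts <- function(dist) {
  validate_pc_dist(dist)
  stats::setNames(dist$nu * dist$lam, dist$labels)
}

#' Mean probabilities of a belief
#'
#' The normalized effective counts `alpha / sum(alpha)`, i.e. the point
#' estimate used for reporting. Equals `lam` by construction.
#'
#' @param dist A [pc_dist()].
#' @return Probability vector over the categories.
#' @export
mean_probabilities <- function(dist) {
  a <- effective_counts(dist)
  a / sum(a)
}

#' Message (geometric-mean) parameters of a belief
#'
#' The parameterization substituted into sum-product messages under
#' variational inference with Dirichlet beliefs:
#' `w_k = exp(digamma(alpha_k) - digamma(sum(alpha)))`, the exponentiated
#' expected log-probability. All weights are positive and their sum is <= 1;
#' they approach the mean probabilities as `nu` grows.
#'
#' @param dist A [pc_dist()].
#' @return Positive weight vector (sub-normalized).
#' @export
message_parameters <- function(dist) {
  a <- effective_counts(dist)
  if (any(a == 0)) {
    stop("degenerate belief: zero effective count has no finite expected log",
         call. = FALSE)
  }
  exp(digamma(a) - digamma(sum(a)))
}

#' Absorb observation counts into a belief
#'
#' The batch-learning primitive: adds (possibly fractional, e.g. posterior
#' expected) counts to the effective Dirichlet counts and renormalizes, so
#' `alpha' = nu*lam + counts`, `nu' = nu + sum(counts)`, `lam' = alpha'/nu'`.
#' The input belief is unchanged.
#'
#' @param dist A [pc_dist()].
#' @param counts Non-negative numeric vector of length K.
#' @return A new [pc_dist()] with the counts absorbed.
#' @export
absorb_counts <- function(dist, counts) {
  validate_pc_dist(dist)
  counts <- as.numeric(counts)
  if (length(counts) != length(dist$lam)) {
    stop("counts length must match the number of categories", call. = FALSE)
  }
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  a <- dist$nu * dist$lam + counts
  nu <- dist$nu + sum(counts)
  pc_dist(a / nu, nu, labels = dist$labels)
}

#' @export
print.pc_dist <- function(x, ...) {
  cat("<pc_dist> nu =", format(x$nu), "\n")
  print(stats::setNames(round(x$lam, 6), x$labels))
  invisible(x)
}

#' Conditional probability table with per-row pseudocounts
#'
#' One categorical belief per parent state, all sharing a child alphabet.
#' Stored as a row-stochastic `lam` matrix (parents x children) plus a
#' per-row pseudocount vector `nu`. Houses the likelihood p(S_t | H_t) and
#' the transition p(H_t | H_t-1).
#'
#' @param lam Row-stochastic numeric matrix (parents x children).
#' @param nu Positive pseudocount, scalar (recycled) or one per row.
#' @param parent_labels,child_labels Category names; default to dimnames.
#' @return An object of class `cond_table`.
#' @examples
#' lik <- cond_table(rbind(pain = c(0.8, 0.2), pain_free = c(0.1, 0.9)),
#'                   nu = 100, child_labels = c("noxious", "harmless"))
#' @export
cond_table <- function(lam, nu, parent_labels = NULL, child_labels = NULL) {
  lam <- as.matrix(lam)
  if (is.null(parent_labels)) {
    parent_labels <- rownames(lam)
    if (is.null(parent_labels)) parent_labels <- paste0("p", seq_len(nrow(lam)))
  }
  if (is.null(child_labels)) {
    child_labels <- colnames(lam)
    if (is.null(child_labels)) child_labels <- paste0("c", seq_len(ncol(lam)))
  }
  nu <- rep_len(as.numeric(nu), nrow(lam))
  dimnames(lam) <- list(parent_labels, child_labels)
  obj <- structure(
    list(parent_labels = as.character(parent_labels),
         child_labels = as.character(child_labels),
         lam = lam, nu = nu),
    class = "cond_table"
  )
  validate_cond_table(obj)
  obj
}

validate_cond_table <- function(x) {
  stopifnot(inherits(x, "cond_table"))
  for (i in seq_len(nrow(x$lam))) {
    validate_pc_dist(table_row(x, i))
  }
  invisible(x)
}

#' Extract one row of a conditional table as a belief
#'
#' @param tab A [cond_table()].
#' @param i Parent index or label.
#' @return The row's [pc_dist()].
#' @export
table_row <- function(tab, i) {
  pc_dist(tab$lam[i, ], tab$nu[[if (is.character(i)) match(i, tab$parent_labels) else i]],
          labels = tab$child_labels)
}

#' @export
print.cond_table <- function(x, ...) {
  cat("<cond_table>", nrow(x$lam), "parent state(s), nu =",
      paste(format(x$nu), collapse = ", "), "\n")
  print(round(x$lam, 6))
  invisible(x)
}

# Parameter matrices in the requested parameterization ------------------

param_vec <- function(dist, parameterization = c("mean", "message")) {
  parameterization <- match.arg(parameterization)
  if (parameterization == "mean") mean_probabilities(dist) else message_parameters(dist)
}

param_mat <- function(tab, parameterization = c("mean", "message")) {
  parameterization <- match.arg(parameterization)
  out <- tab$lam
  if (parameterization == "message") {
    for (i in seq_len(nrow(out))) {
      out[i, ] <- message_parameters(table_row(tab, i))
    }
  }
  out
}
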