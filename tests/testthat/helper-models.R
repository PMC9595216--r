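# Shared fixture builders. Everything is generated in code; no stored data.

H <- c("pain", "pain_free")
S <- c("noxious", "harmless")

uniform_model <- function(n_steps = 20, nu = 2) {
  chain_model(
    pc_dist(c(0.5, 0.5), nu, labels = H),
    cond_table(rbind(c(0.5, 0.5), c(0.5, 0.5)), nu,
               parent_labels = H, child_labels = H),
    cond_table(rbind(c(0.5, 0.5), c(0.5, 0.5)), nu,
               parent_labels = H, child_labels = S),
    n_steps
  )
}

# Random strictly-positive model for property tests (draws from the current
# RNG stream; callers set the seed).
random_model <- function(max_steps = 12) {
  rdist <- function(n) {
    x <- stats::rgamma(n, 1) + 0.05
    x / sum(x)
  }
  n <- sample.int(max_steps, 1)
  chain_model(
    pc_dist(rdist(2), stats::runif(1, 5, 200), labels = H),
    cond_table(rbind(rdist(2), rdist(2)), stats::runif(2, 5, 200),
               parent_labels = H, child_labels = H),
    cond_table(rbind(rdist(2), rdist(2)), stats::runif(2, 5, 200),
               parent_labels = H, child_labels = S),
    n
  )
}

random_schedule <- function(n_steps) {
  sample(c(S, "unobserved"), n_steps, replace = TRUE)
}

# Single-node model from the exposure-therapy worked example:
# prior (0.7, 0.3), accurate likelihood (0.8/0.2, 0.1/0.9).
single_node_example <- function() {
  chain_model(
    pc_dist(c(0.7, 0.3), 100, labels = H),
    cond_table(rbind(c(0.3, 0.7), c(0.175, 0.825)), 100,
               parent_labels = H, child_labels = H),
    cond_table(rbind(c(0.8, 0.2), c(0.1, 0.9)), 100,
               parent_labels = H, child_labels = S),
    1
  )
}
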