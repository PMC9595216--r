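test_that("expected_counts partitions the sweep as specified", {
  # single node, harmless observation: prior counts = q(H1),
  # likelihood counts all in the harmless column, no transition counts
  m <- single_node_example()
  obs <- "harmless"
  sw <- propagate(m, obs, "mean")
  cs <- expected_counts(sw, obs, m)
  expect_equal(unname(cs$prior_counts), c(0.14 / 0.41, 0.27 / 0.41),
               tolerance = 1e-10)
  expect_equal(unname(cs$likelihood_counts[, "harmless"]),
               unname(cs$prior_counts))
  expect_equal(sum(cs$likelihood_counts[, "noxious"]), 0)
  expect_equal(sum(cs$transition_counts), 0)

  # all nodes unobserved: no likelihood counts at all
  m8 <- preset_observer("healthy", 8)
  obs8 <- rep("unobserved", 8)
  cs8 <- expected_counts(propagate(m8, obs8, "mean"), obs8, m8)
  expect_equal(sum(cs8$likelihood_counts), 0)
  expect_equal(sum(cs8$prior_counts), 1)
  expect_equal(sum(cs8$transition_counts), 7)

  # N = 2: transition counts equal the single pairwise table
  m2 <- preset_observer("healthy", 2)
  obs2 <- c("noxious", "harmless")
  sw2 <- propagate(m2, obs2, "mean")
  cs2 <- expected_counts(sw2, obs2, m2)
  expect_equal(cs2$transition_counts, sw2$pairwise[1, , ])
})

test_that("batch_update absorbs counts row-wise and is identity on zeros", {
  m <- preset_observer("healthy", 2)
  obs <- c("noxious", "harmless")
  cs <- expected_counts(propagate(m, obs, "mean"), obs, m)
  m2 <- batch_update(m, cs)
  expect_equal(m2$prior$nu, 101)
  expect_equal(sum(m2$transition$nu), sum(m$transition$nu) + 1)  # N - 1 = 1
  expect_equal(sum(m2$likelihood$nu), sum(m$likelihood$nu) + 2)  # 2 observed
  expect_equal(m$prior$nu, 100)  # input unchanged

  zero <- cs
  zero$prior_counts[] <- 0
  zero$transition_counts[] <- 0
  zero$likelihood_counts[] <- 0
  # zero prior counts are not produced by sweeps, but absorption tolerates them
  m3 <- batch_update(m, zero)
  expect_equal(m3$prior$lam, m$prior$lam)
  expect_equal(m3$transition$lam, m$transition$lam)
  expect_equal(m3$likelihood$lam, m$likelihood$lam)
})

test_that("a fully noxious sweep doubles the chronic pain-row pseudocount", {
  # chronic likelihood pain row nu = 20; with q(pain) ~ 1 at every node a
  # 20-step all-noxious sweep adds ~20 noxious counts: alpha (12,8) -> (~32,8)
  c <- preset_observer("chronic")
  # sharpen the prior so q(pain) ~ 1 everywhere
  sure <- chain_model(pc_dist(c(1 - 1e-12, 1e-12), 1e6, labels = H),
                      cond_table(rbind(c(1 - 1e-9, 1e-9), c(1 - 1e-9, 1e-9)),
                                 100, parent_labels = H, child_labels = H),
                      c$likelihood, 20)
  obs <- rep("noxious", 20)
  cs <- expected_counts(propagate(sure, obs, "mean"), obs, sure)
  up <- batch_update(sure, cs)
  expect_equal(up$likelihood$nu[1], 40, tolerance = 1e-3)
  expect_gt(up$likelihood$lam["pain", "noxious"], 0.6)
})

test_that("count conservation across a learning run", {
  m <- preset_observer("healthy")
  sched <- observation_schedule("mixed", 20)  # 12 observed nodes
  n_trials <- 7
  run <- run_learning(m, rep(list(sched), n_trials))
  fin <- run$final_model
  expect_equal(fin$prior$nu, 100 + n_trials)
  expect_equal(sum(fin$transition$nu), 200 + n_trials * 19)
  expect_equal(sum(fin$likelihood$nu), 200 + n_trials * 12)
  expect_equal(dim(run$trajectories), c(n_trials, 20))
  expect_true(all(run$trajectories >= 0 & run$trajectories <= 1))
})

test_that("no-evidence learning leaves the trajectory at the stationary prior", {
  m <- preset_observer("healthy", 10)
  sched <- obs_schedule(rep("unobserved", 10), m)
  run <- run_learning(m, list(sched), parameterization = "mean")
  expect_lt(max(abs(run$trajectories[1, ] - 0.2)), 1e-12)
  expect_equal(run$final_model$prior$nu, 101)
  expect_error(run_learning(m, list()), "empty")
})

test_that("free energy is non-increasing under repeated infer/update cycles", {
  for (par in c("mean", "message")) {
    m <- preset_observer("healthy")
    sched <- observation_schedule("mixed", 20)
    run <- run_learning(m, rep(list(sched), 40), parameterization = par)
    expect_true(all(diff(run$free_energies) <= 1e-9),
                label = paste("descent under", par, "parameterization"))
  }
})

test_that("complete-data counts recover the generating parameters", {
  # Parameter recovery for the generative sampler: hidden paths and emissions
  # are both used (from an exactly uniform start, posterior-expected counts
  # cannot break the label symmetry, so recovery is assessed on the
  # complete-data sufficient statistics).
  truth <- preset_observer("healthy")
  for (sd in 1:3) {
    seqs <- sample_generative(truth, seed = 1000 * sd, n_sequences = 200)
    m <- uniform_model(20, nu = 2)
    for (s in seqs) {
      m <- batch_update(m, complete_data_counts(s$hidden, s$obs, m))
    }
    expect_lt(max(abs(m$transition$lam - truth$transition$lam)), 0.05)
    expect_lt(max(abs(m$likelihood$lam - truth$likelihood$lam)), 0.05)
  }
})

test_that("learning runs serialize to a tidy data frame", {
  run <- run_learning(preset_observer("chronic"),
                      rep(list(observation_schedule("mixed", 20)), 3))
  df <- as.data.frame(run)
  expect_equal(nrow(df), 60)
  expect_equal(names(df), c("trial", "time_step", "q_pain", "free_energy"))
  expect_equal(df$q_pain[df$trial == 2], unname(run$trajectories[2, ]))
})
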