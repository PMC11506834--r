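# Protocol-level tests on small fixtures and shortened runs (the full
# published protocol is exercised in test-acceptance.R).

test_that("trial protocol validates its arithmetic", {
  pr <- trial_protocol()
  expect_equal(pr$n_steps, 200L)
  expect_equal(pr$report_trials, c(1L, 2L, 3L, 20L, 300L))
  expect_error(trial_protocol(episode_length = 1.995), "multiple")
  expect_error(trial_protocol(report_trials = c(1, 500)), "1..n_trials")
})

test_that("a trial runs exactly n_steps and ends at 2.00 s", {
  fix <- build_fixture("two_link_arm")
  grid <- basis_grid(2, layout = "tiled")
  fcm <- fcm_model("ml", plant = fix$plant, ml_sign = "narrative")
  p <- learner_params()
  set.seed(1)
  res <- run_trial(fix$plant, grid, critic_new(grid),
                   actor_new(grid, fix$plant$n_muscles), fcm, p,
                   init_angles = c(-60, 30))
  expect_equal(res$steps, 200L)
  expect_equal(nrow(res$angles), 200)
  expect_false(res$diverged)
})

test_that("an equilibrium start under no gravity stays stabilized", {
  # symmetric antagonists at equal activation cancel, so the target posture
  # is an equilibrium; equal activations require the exploration noise to
  # be attenuated, so start from a converged (high) value surface where
  # the noise scale exp(-0.5 V) is negligible
  fix <- build_fixture("two_link_arm", overrides = list(gravity_scale = 0))
  grid <- basis_grid(2, layout = "tiled")
  fcm <- fcm_model("none", plant = fix$plant)
  p <- learner_params()
  critic <- critic_new(grid)
  critic$v <- rep(50, grid$K)
  set.seed(2)
  res <- run_trial(fix$plant, grid, critic,
                   actor_new(grid, fix$plant$n_muscles), fcm, p,
                   init_angles = fix$plant$targets, learn = FALSE)
  expect_equal(unname(res$final_error), c(0, 0), tolerance = 1e-6)
  expect_equal(res$stabilized, 2)
})

test_that("stabilization counting is inclusive at exactly 5 degrees", {
  expect_equal(count_stabilized(c(0, 0, 0, 0, 0)), 5)
  expect_equal(count_stabilized(c(4.9, -4.9, 5.1, 0, 0)), 4)
  expect_equal(count_stabilized(c(5, -5, 5.0001, -5.0001)), 2)
  expect_equal(count_stabilized(rep(10, 5)), 0)
})

test_that("training is deterministic given the seed", {
  fix <- build_fixture("two_link_arm")
  pr <- trial_protocol(n_trials = 5, report_trials = c(1, 5))
  r1 <- run_training(fix, "ml", seed = 42, protocol = pr,
                     ml_sign = "narrative", record_report = FALSE)
  r2 <- run_training(fix, "ml", seed = 42, protocol = pr,
                     ml_sign = "narrative", record_report = FALSE)
  expect_identical(r1$final_errors, r2$final_errors)
  expect_identical(r1$critic$v, r2$critic$v)
  expect_identical(r1$actor$w, r2$actor$w)
  r3 <- run_training(fix, "ml", seed = 43, protocol = pr,
                     ml_sign = "narrative", record_report = FALSE)
  expect_false(identical(r1$final_errors, r3$final_errors))
})

test_that("reported counts are invariant to history retention", {
  fix <- build_fixture("two_link_arm")
  pr <- trial_protocol(n_trials = 4, report_trials = c(1, 4))
  r1 <- run_training(fix, "ml", seed = 7, protocol = pr,
                     ml_sign = "narrative", record_report = TRUE)
  r2 <- run_training(fix, "ml", seed = 7, protocol = pr,
                     ml_sign = "narrative", record_report = FALSE)
  expect_identical(r1$counts, r2$counts)
  expect_identical(r1$final_errors, r2$final_errors)
})

test_that("weights persist across trials and snapshots capture them", {
  fix <- build_fixture("two_link_arm")
  pr <- trial_protocol(n_trials = 3, report_trials = c(1, 3))
  run <- run_training(fix, "ml", seed = 1, protocol = pr,
                      ml_sign = "narrative")
  expect_false(identical(run$snapshots[["1"]]$v, run$snapshots[["3"]]$v))
  expect_identical(run$snapshots[["3"]]$v, run$critic$v)
  expect_identical(run$snapshots[["3"]]$w, run$actor$w)
})

test_that("frozen-policy prediction never mutates the network", {
  fix <- build_fixture("two_link_arm")
  pr <- trial_protocol(n_trials = 3, report_trials = 3)
  run <- run_training(fix, "ml", seed = 1, protocol = pr,
                      ml_sign = "narrative")
  net <- list(grid = run$grid, critic = run$critic, actor = run$actor)
  v_before <- serialize(net, NULL)
  fcm <- fcm_model("ml", plant = fix$plant, ml_sign = "narrative")
  res <- predict_posture(fix$plant, net, fcm, c(-80, 50), seed = 9)
  expect_identical(serialize(net, NULL), v_before)
  expect_identical(res$critic$v, run$critic$v)
  expect_equal(nrow(res$activations), 200)
  # rollout is reproducible under its seed
  res2 <- predict_posture(fix$plant, net, fcm, c(-80, 50), seed = 9)
  expect_identical(res$angles, res2$angles)
})

test_that("non-finite states abort the trial and score zero", {
  pl <- pendulum_plant()
  # direct detection in the integrator, naming the joint
  st <- plant_state(pl, 10)
  st$velocities <- NaN
  expect_error(plant_step(pl, st, c(0, 0)), "diverged at joint 'J1'")
  # end-to-end: a pathological ceiling poisons the dynamics; the trial is
  # aborted and scored as zero joints stabilized
  grid <- basis_grid(1)
  bad_fcm <- structure(list(kind = "none",
                            ceiling = function(angles, dtheta) c(NaN, NaN)),
                       class = "fcm")
  set.seed(1)
  res <- run_trial(pl, grid, critic_new(grid), actor_new(grid, 2), bad_fcm,
                   learner_params(), init_angles = 10)
  expect_true(res$diverged)
  expect_equal(res$stabilized, 0)
})

test_that("summary tables assemble and round-trip", {
  expect_equal(nrow(summarize_runs(list())), 0)
  fix <- build_fixture("two_link_arm")
  pr <- trial_protocol(n_trials = 2, report_trials = c(1, 2))
  runs <- lapply(c("ml", "none"), function(k)
    run_training(fix, k, seed = 0, protocol = pr,
                 ml_sign = "narrative", record_report = FALSE))
  tab <- summarize_runs(runs)
  expect_equal(nrow(tab), 2)
  expect_named(tab, c("algorithm", "fcm", "fixture", "seed",
                      "trial_1", "trial_2"))
  expect_true(all(tab$trial_1 %in% 0:2))
  for (ext in c(".json", ".csv")) {
    path <- withr::local_tempfile(fileext = ext)
    write_summary(tab, path)
    back <- read_summary(path)
    expect_equal(back$fcm, tab$fcm)
    expect_equal(back$trial_2, tab$trial_2)
  }
})
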