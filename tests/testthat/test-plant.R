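test_that("muscle_length follows the constant-moment-arm linearization", {
  pl <- pendulum_plant(arm = 0.02)
  # +10 degrees from reference with a 0.02 m arm shortens by 0.02*10*pi/180
  l <- muscle_lengths(pl, 10)
  expect_equal(unname(l["flex"]), 0.3 - 0.02 * (10 * pi / 180),
               tolerance = 1e-12)
  expect_equal(unname(l["ext"]), 0.3 + 0.02 * (10 * pi / 180),
               tolerance = 1e-12)
  # identity at the reference posture
  expect_equal(unname(muscle_lengths(pl, 0)), c(0.3, 0.3))
})

test_that("multiarticular lengths match a per-joint summation oracle", {
  pl <- two_joint_plant()
  angles <- c(5, 5)
  l <- muscle_lengths(pl, angles)
  # independent brute-force summation over joints
  for (m in seq_len(pl$n_muscles)) {
    expect_l <- unname(pl$lref[m])
    for (j in seq_len(pl$n_joints))
      expect_l <- expect_l - pl$arms[m, j] * (angles[j] * pi / 180)
    expect_equal(unname(l[m]), expect_l, tolerance = 1e-12)
  }
})

test_that("length_rates vanish exactly at the target posture", {
  pl <- two_joint_plant()
  expect_equal(unname(length_rates(pl, pl$targets)), rep(0, 6))
  # recomputation oracle 10 degrees off target
  ang <- pl$targets + 10
  l0 <- equilibrium_lengths(pl)
  expect_equal(length_rates(pl, ang),
               (muscle_lengths(pl, ang) - l0) / l0, tolerance = 1e-12)
  # definition check: l = 1.02 l0 -> 0.02
  expect_equal(unname((1.02 * l0[1] - l0[1]) / l0[1]), 0.02)
})

test_that("zero activation and zero gravity leave the state unchanged", {
  pl <- pendulum_plant(gravity = 0)
  st <- plant_state(pl, 30)
  nxt <- plant_step(pl, st, c(0, 0))
  expect_equal(nxt$angles, st$angles)
  expect_equal(nxt$velocities, st$velocities)
  expect_equal(nxt$time, 0.01)
})

test_that("passive pendulum period matches the small-angle closed form", {
  I <- 0.05; G <- 0.5
  pl <- pendulum_plant(inertia = I, damping = 0, gravity = G)
  st <- plant_state(pl, 2)  # 2 degrees: small-angle regime
  n <- 20000
  ang <- numeric(n)
  for (k in seq_len(n)) {
    st <- plant_step(pl, st, c(0, 0))
    ang[k] <- st$angles
  }
  # count zero crossings to estimate the period over many cycles
  crossings <- which(diff(sign(ang)) != 0)
  period <- 2 * diff(range(crossings)) * 0.01 / (length(crossings) - 1)
  expect_equal(period, 2 * pi * sqrt(I / G), tolerance = 0.02)
})

test_that("equal co-activation of a symmetric antagonist pair is torque-free", {
  pl <- pendulum_plant(gravity = 0, damping = 0)
  st <- plant_state(pl, 25)
  for (u in c(0.2, 0.9)) {
    nxt <- plant_step(pl, st, c(u, u))
    expect_equal(unname(nxt$velocities), 0)
  }
})

test_that("identical inputs give bit-identical trajectories", {
  pl <- two_joint_plant()
  act <- matrix(runif(50 * 6), 50)
  roll <- function() {
    st <- plant_state(pl, c(10, -30))
    out <- numeric(0)
    for (k in 1:50) { st <- plant_step(pl, st, act[k, ]); out <- c(out, st$angles) }
    out
  }
  expect_identical(roll(), roll())
})

test_that("passive damped motion never gains mechanical energy", {
  pl <- pendulum_plant(inertia = 0.05, damping = 0.2, gravity = 0.5)
  st <- plant_state(pl, 60)
  energy <- function(s) {
    om <- s$velocities * pi / 180
    0.5 * 0.05 * om^2 + 0.5 * (1 - cos(s$angles * pi / 180))
  }
  e_prev <- energy(st)
  for (k in 1:500) {
    st <- plant_step(pl, st, c(0, 0))
    e <- energy(st)
    expect_lte(e, e_prev * (1 + 1e-6))
    e_prev <- e
  }
})

test_that("joint torque is additive over muscles", {
  pl <- two_joint_plant()
  st <- plant_state(pl, c(0, 0))
  u <- runif(6)
  # velocity change after one step ~ torque; compare all-muscles vs summed
  dv_all <- plant_step(pl, st, u)$velocities - st$velocities
  dv_sum <- rep(0, 2)
  for (m in 1:6) {
    um <- rep(0, 6); um[m] <- u[m]
    dv_sum <- dv_sum + plant_step(pl, st, um)$velocities - st$velocities
  }
  expect_equal(dv_all, dv_sum, tolerance = 1e-9)
})

test_that("muscle lengths stay consistent with angles after stepping", {
  pl <- two_joint_plant()
  st <- plant_state(pl, c(40, -100))
  for (k in 1:20) st <- plant_step(pl, st, runif(6))
  expect_equal(st$muscle_lengths, muscle_lengths(pl, st$angles))
})

test_that("angles clamp at range stops with velocity zeroed", {
  pl <- pendulum_plant(gravity = 0)
  st <- plant_state(pl, 169.5)
  st$velocities <- 5000
  nxt <- plant_step(pl, st, c(0, 0))
  expect_equal(unname(nxt$angles), 170)
  expect_equal(unname(nxt$velocities), 0)
})

test_that("invalid configurations are rejected with named diagnostics", {
  expect_error(joint_spec("J", c(10, -10), 0, 0.1), "min < max")
  expect_error(joint_spec("J", c(-10, 10), 20, 0.1), "target_angle")
  expect_error(joint_spec("J", c(-10, 10), 0, -1), "inertia")
  expect_error(muscle_spec("m", 100, 0.3, c(J1 = 0)), "nonzero")
  # uncontrollable: both muscles pull the same way
  expect_error(plant_config(
    list(joint_spec("J1", c(-90, 90), 0, 0.05)),
    list(muscle_spec("a", 100, 0.3, c(J1 = 0.02)),
         muscle_spec("b", 100, 0.3, c(J1 = 0.01)))), "controllable")
  # arms so large the muscle goes slack within the range
  expect_error(plant_config(
    list(joint_spec("J1", c(-170, 170), 0, 0.05)),
    list(muscle_spec("a", 100, 0.05, c(J1 = 0.02)),
         muscle_spec("b", 100, 0.05, c(J1 = -0.02)))), "non-positive")
})

test_that("plant YAML serialization round-trips", {
  pl <- two_joint_plant()
  path <- withr::local_tempfile(fileext = ".yaml")
  write_plant_yaml(pl, path)
  pl2 <- read_plant_yaml(path)
  expect_equal(pl2$arms, pl$arms)
  expect_equal(pl2$targets, pl$targets)
  expect_equal(pl2$gcoeff, pl$gcoeff)
})

test_that("trajectory CSV has the documented column layout", {
  path <- withr::local_tempfile(fileext = ".csv")
  write_trajectories(c(0.01, 0.02), matrix(1:4, 2), matrix(5:8, 2),
                     c("A", "B"), path)
  df <- read.csv(path)
  expect_named(df, c("time_s", "A_deg", "B_deg", "A_degps", "B_degps"))
  expect_equal(nrow(df), 2)
})
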