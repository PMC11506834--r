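# Experiment protocols: multi-trial learning runs with stabilization
# scoring, and frozen-policy posture-change predictions.
#
# Per-step contract (the standard continuous-time actor-critic sequence):
#   observe s(t) -> basis, V, actions, ceiling, noise, activations
#   -> advance plant -> observe s(t+1) -> reward from s(t) and u(t)
#   -> TD error -> traces updated with b(s(t)) -> critic, then actor.
# Traces reset to zero at every trial start; weights persist across trials.

#' Trial protocol parameters
#'
#' Defaults: 2.0 s episodes at 0.01 s (200 steps), 300 trials, results
#' reported at trials 1, 2, 3, 20 and 300.
#'
#' @param episode_length Seconds; must be an integer multiple of `dt`.
#' @param dt Step, seconds.
#' @param n_trials Number of learning trials.
#' @param report_trials Trials at which stabilized counts and network
#'   snapshots are recorded.
#' @return A `trial_protocol` list.
#' @export
trial_protocol <- function(episode_length = 2.0, dt = 0.01, n_trials = 300,
                           report_trials = c(1, 2, 3, 20, 300)) {
  n_steps <- episode_length / dt
  if (abs(n_steps - round(n_steps)) > 1e-9)
    stop2("episode_length must be an integer multiple of dt")
  report_trials <- sort(unique(as.integer(report_trials)))
  if (any(report_trials < 1) || any(report_trials > n_trials))
    stop2("report_trials must lie in 1..n_trials")
  structure(list(episode_length = episode_length, dt = dt,
                 n_steps = as.integer(round(n_steps)), n_trials = n_trials,
                 report_trials = report_trials),
            class = "trial_protocol")
}

#' Run one trial (episode)
#'
#' Runs `n_steps` learning (or frozen) steps from the given initial
#' posture. Exploration noise is drawn from the calling R session's RNG
#' stream; seed management belongs to the caller.
#'
#' @param plant A `posture_plant`.
#' @param grid,critic,actor Network pieces (see [basis_grid()]).
#' @param fcm An [fcm_model()].
#' @param params [learner_params()].
#' @param init_angles Initial joint angles, degrees.
#' @param targets Target angles used for the state/reward (defaults to the
#'   plant's neutral-posture targets; override to move the reward target
#'   without touching the feedback model's equilibrium lengths).
#' @param n_steps Steps per episode (default 200, i.e. 2.0 s).
#' @param learn If `FALSE`, weights are left untouched (frozen policy).
#' @param record If `TRUE`, per-step activations, reward, TD error and
#'   value are retained.
#' @return A `trial_result`: final windowed errors, stabilized count,
#'   angle/velocity histories, updated critic and actor, and (optionally)
#'   full learning histories. If the plant diverges the trial is aborted
#'   and scored as zero joints stabilized (`diverged = TRUE`).
#' @export
run_trial <- function(plant, grid, critic, actor, fcm, params, init_angles,
                      targets = plant$targets, n_steps = 200L,
                      learn = TRUE, record = FALSE) {
  nj <- plant$n_joints
  nm <- plant$n_muscles
  state <- plant_state(plant, init_angles)
  e <- numeric(grid$K)
  ang_hist <- matrix(NA_real_, n_steps, nj,
                     dimnames = list(NULL, plant$joint_names))
  vel_hist <- ang_hist
  if (record) {
    u_hist <- matrix(NA_real_, n_steps, nm,
                     dimnames = list(NULL, plant$muscle_names))
    r_hist <- numeric(n_steps); d_hist <- numeric(n_steps)
    v_hist <- numeric(n_steps); sig_hist <- numeric(n_steps)
  }
  s <- make_state(state$angles, state$velocities, targets)
  b <- ngn_basis(grid, s)
  diverged <- FALSE
  steps_done <- 0L
  for (t in seq_len(n_steps)) {
    V <- ngn_value(critic, b)
    a <- ngn_action(actor, b)
    u_max <- fcm$ceiling(state$angles, s[seq_len(nj)])
    n <- acrl_noise(nm)
    u <- activation(a, V, n, u_max, params)
    nxt <- tryCatch(plant_step(plant, state, u, params$dt),
                    error = function(err) NULL)
    if (is.null(nxt)) { diverged <- TRUE; break }
    state <- nxt
    s2 <- make_state(state$angles, state$velocities, targets)
    b2 <- ngn_basis(grid, s2)
    if (learn) {
      r <- acrl_reward(s, u, params)
      V2 <- ngn_value(critic, b2)
      delta <- td_error(r, V, V2, params)
      e <- update_traces(e, b, params)
      critic <- update_critic(critic, delta, e, params)
      actor <- update_actor(actor, delta, n, V, b, params)
    }
    ang_hist[t, ] <- state$angles
    vel_hist[t, ] <- state$velocities
    if (record) {
      u_hist[t, ] <- u
      if (learn) { r_hist[t] <- r; d_hist[t] <- delta }
      v_hist[t] <- V; sig_hist[t] <- exp(-0.5 * V)
    }
    s <- s2
    b <- b2
    steps_done <- t
  }
  if (diverged) {
    final_error <- rep(Inf, nj)
  } else {
    win <- max(1L, n_steps - 19L):n_steps  # final 0.2 s
    final_error <- colMeans(ang_hist[win, , drop = FALSE]) - targets
  }
  res <- list(init_angles = init_angles, targets = targets,
              final_error = final_error,
              stabilized = count_stabilized(final_error),
              angles = ang_hist, velocities = vel_hist,
              diverged = diverged, steps = steps_done,
              critic = critic, actor = actor)
  if (record) {
    res$activations <- u_hist
    res$reward <- r_hist; res$td_error <- d_hist
    res$value <- v_hist; res$noise_scale <- sig_hist
  }
  structure(res, class = "trial_result")
}

#' Count joint motions stabilized within the +/-5 degree band
#'
#' The readout is the mean signed error over the final 0.2 s of the
#' episode (20 samples), inclusive at exactly 5 degrees.
#'
#' @param final_error Per-joint windowed errors (degrees), or a
#'   `trial_result`.
#' @return Integer count.
#' @export
count_stabilized <- function(final_error) {
  if (inherits(final_error, "trial_result"))
    final_error <- final_error$final_error
  sum(abs(final_error) <= 5)
}

#' Run a full learning experiment
#'
#' Sequential trials with persistent weights; initial joint angles are
#' drawn uniformly from each joint's range using an RNG stream independent
#' of the exploration-noise stream (both derived from `seed`), so adding
#' or removing logging never shifts the noise sequence.
#'
#' @param fixture A fixture list from [build_fixture()] (or any list with
#'   `plant`, `table`).
#' @param fcm_kind `"ml"`, `"ja"` or `"none"`.
#' @param seed Integer run seed.
#' @param params [learner_params()].
#' @param protocol [trial_protocol()].
#' @param targets Optional reward/state target override (degrees).
#' @param ml_sign Slope convention for the muscle-length model, see
#'   [fcm_ml()].
#' @param grid Optional pre-built [basis_grid()].
#' @param record_report Retain full histories at report trials.
#' @return A `training_run`: per-trial stabilized counts and final errors,
#'   stabilized counts + network snapshots at the report trials, the final
#'   critic/actor, and run metadata.
#' @export
run_training <- function(fixture, fcm_kind = c("ml", "ja", "none"), seed = 0,
                         params = learner_params(),
                         protocol = trial_protocol(),
                         targets = NULL, ml_sign = "as_printed",
                         grid = NULL, record_report = TRUE) {
  fcm_kind <- match.arg(fcm_kind)
  plant <- fixture$plant
  nj <- plant$n_joints
  # experiments default to the tiled layout: the value function and the
  # per-muscle policies must resolve WHICH joint motion is in error, which
  # the shared (replicated-center) layout cannot represent -- see vignette
  if (is.null(grid)) grid <- basis_grid(nj, layout = "tiled")
  if (is.null(targets)) targets <- plant$targets
  fcm <- fcm_model(fcm_kind, plant = plant, table = fixture$table,
                   ml_sign = ml_sign, u_max_default = params$u_max_default)
  critic <- critic_new(grid)
  actor <- actor_new(grid, plant$n_muscles)

  set.seed(child_seed(seed, 1))
  init <- matrix(stats::runif(protocol$n_trials * nj,
                              rep(plant$range_lo, each = protocol$n_trials),
                              rep(plant$range_hi, each = protocol$n_trials)),
                 protocol$n_trials, nj, dimnames = list(NULL, plant$joint_names))

  counts <- integer(protocol$n_trials)
  errors <- matrix(NA_real_, protocol$n_trials, nj,
                   dimnames = list(NULL, plant$joint_names))
  snapshots <- list()
  report_results <- list()
  set.seed(child_seed(seed, 2))
  for (tr in seq_len(protocol$n_trials)) {
    keep <- tr %in% protocol$report_trials
    res <- run_trial(plant, grid, critic, actor, fcm, params, init[tr, ],
                     targets = targets, n_steps = protocol$n_steps,
                     learn = TRUE, record = keep && record_report)
    critic <- res$critic
    actor <- res$actor
    counts[tr] <- res$stabilized
    errors[tr, ] <- res$final_error
    if (keep) {
      key <- as.character(tr)
      snapshots[[key]] <- list(v = critic$v, w = actor$w)
      res$critic <- res$actor <- NULL  # stored in snapshots
      report_results[[key]] <- res
    }
  }
  structure(list(
    counts = stats::setNames(counts[protocol$report_trials],
                             protocol$report_trials),
    stabilized_per_trial = counts,
    final_errors = errors,
    init_angles = init,
    snapshots = snapshots,
    report_results = report_results,
    grid = grid, critic = critic, actor = actor,
    meta = list(fixture = fixture$name %||% "custom", fcm = fcm_kind,
                ml_sign = ml_sign, seed = seed, algorithm = "acrl_ngn",
                n_trials = protocol$n_trials, targets = targets,
                stabilization_readout = "mean signed error, final 0.2 s",
                params = unclass(params))),
    class = "training_run")
}

#' Frozen-policy posture-change prediction
#'
#' Rolls out 2 s from a fixed initial posture using trained weights with
#' learning switched off. Exploration noise stays active with scale
#' `exp(-0.5 V)`, and the activation ceiling comes from the given feedback
#' model, exactly as during training. Weights are never mutated.
#'
#' @param plant A `posture_plant`.
#' @param network List with `grid`, `critic`, `actor` (e.g. from
#'   [read_network_json()] or a `training_run`).
#' @param fcm An [fcm_model()].
#' @param init_angles Initial posture, degrees (clamped to ranges).
#' @param seed Seed for the rollout noise.
#' @param params [learner_params()].
#' @param n_steps Rollout length (default 200 = 2.0 s).
#' @return A `trial_result` with histories and final errors.
#' @export
predict_posture <- function(plant, network, fcm, init_angles, seed = 0,
                            params = learner_params(), n_steps = 200L) {
  set.seed(child_seed(seed, 3))
  run_trial(plant, network$grid, network$critic, network$actor, fcm, params,
            clip(init_angles, plant$range_lo, plant$range_hi),
            n_steps = n_steps, learn = FALSE, record = TRUE)
}

#' Assemble a summary table of stabilized counts
#'
#' One row per (algorithm, feedback model, fixture) condition, one column
#' per report trial, cells = stabilized joint-motion counts.
#'
#' @param runs List of `training_run` objects.
#' @return A `data.frame` in the summary layout.
#' @export
summarize_runs <- function(runs) {
  if (!length(runs))
    return(data.frame(algorithm = character(), fcm = character(),
                      fixture = character()))
  rows <- lapply(runs, function(r) {
    cells <- as.list(r$counts)
    names(cells) <- paste0("trial_", names(r$counts))
    c(list(algorithm = r$meta$algorithm, fcm = r$meta$fcm,
           fixture = r$meta$fixture, seed = r$meta$seed), cells)
  })
  do.call(rbind, lapply(rows, function(x)
    as.data.frame(x, stringsAsFactors = FALSE)))
}

#' Write / read a summary table (JSON round trip is lossless)
#' @param tab Data frame from [summarize_runs()].
#' @param path Output path (`.json` or `.csv` decides the format).
#' @return `read_summary` returns the data frame.
#' @export
write_summary <- function(tab, path) {
  if (grepl("\\.json$", path))
    jsonlite::write_json(tab, path, dataframe = "rows", digits = NA)
  else utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_summary
#' @export
read_summary <- function(path) {
  if (grepl("\\.json$", path))
    as.data.frame(jsonlite::read_json(path, simplifyVector = TRUE))
  else utils::read.csv(path)
}
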