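# Run configuration: YAML schema, validation with provenance-tagged
# defaults, and the command-line entry point.

# default values with their provenance ("published" = printed operating
# point of the original controller; "artifact" = this package's choice)
config_schema <- function() {
  list(
    plant = list(default = "upper_limb_analog", provenance = "artifact",
                 check = function(x) is.character(x) || is.list(x)),
    fcm = list(default = "ml", provenance = "artifact",
               check = function(x) x %in% c("ml", "ja", "none")),
    ml_sign = list(default = "as_printed", provenance = "artifact",
                   check = function(x) x %in% c("as_printed", "narrative")),
    ja_table = list(default = NULL, provenance = "artifact",
                    check = function(x) is.null(x) || is.character(x)),
    seed = list(default = 0, provenance = "artifact",
                check = function(x) is.numeric(x) && x == round(x)),
    out_dir = list(default = ".", provenance = "artifact",
                   check = is.character),
    layout = list(default = "tiled", provenance = "artifact",
                  check = function(x) x %in% c("shared", "tiled")),
    learner = list(default = list(), provenance = "published",
                   check = is.list),
    protocol = list(default = list(), provenance = "published",
                    check = is.list))
}

learner_keys <- c("alpha_v", "alpha_a", "tau", "kappa", "c", "sigma_r",
                  "A", "B", "u_max_default", "dt")
protocol_keys <- c("episode_length", "dt", "n_trials", "report_trials")

#' Load and validate a run configuration
#'
#' Unknown keys are rejected by name. Every omitted key is filled from
#' the defaults (the published controller constants for the learner and
#' protocol blocks; package choices elsewhere), and the provenance of
#' each default is recorded in the returned object's `provenance` field.
#'
#' @param path YAML file; an empty file yields the full default config.
#' @return A `run_config` list with elements `plant`, `fcm`, `ml_sign`,
#'   `ja_table`, `seed`, `out_dir`, `layout`, `learner`
#'   ([learner_params()]), `protocol` ([trial_protocol()]).
#' @export
load_config <- function(path) {
  raw <- if (file.exists(path)) yaml::read_yaml(path) else
    stop2("config file not found: ", path)
  if (is.null(raw)) raw <- list()
  as_run_config(raw)
}

#' @rdname load_config
#' @param raw Named list with the same structure as the YAML document.
#' @export
as_run_config <- function(raw = list()) {
  schema <- config_schema()
  unknown <- setdiff(names(raw), names(schema))
  if (length(unknown))
    stop2("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg <- list()
  prov <- list()
  for (key in names(schema)) {
    val <- raw[[key]] %||% schema[[key]]$default
    if (!is.null(val) && !schema[[key]]$check(val))
      stop2("config key '", key, "' fails validation")
    cfg[[key]] <- val
    prov[[key]] <- if (key %in% names(raw)) "user" else schema[[key]]$provenance
  }
  bad <- setdiff(names(cfg$learner), learner_keys)
  if (length(bad)) stop2("unknown learner key(s): ", paste(bad, collapse = ", "))
  bad <- setdiff(names(cfg$protocol), protocol_keys)
  if (length(bad)) stop2("unknown protocol key(s): ", paste(bad, collapse = ", "))
  cfg$learner <- do.call(learner_params, cfg$learner)
  cfg$protocol <- do.call(trial_protocol, cfg$protocol)
  cfg$provenance <- prov
  structure(cfg, class = "run_config")
}

#' Save a run configuration as YAML (round-trips through [load_config()])
#' @param cfg A `run_config`.
#' @param path Output path.
#' @export
save_config <- function(cfg, path) {
  out <- list(plant = cfg$plant, fcm = cfg$fcm, ml_sign = cfg$ml_sign,
              seed = cfg$seed, out_dir = cfg$out_dir, layout = cfg$layout,
              learner = unclass(cfg$learner),
              protocol = unclass(cfg$protocol)[protocol_keys])
  if (!is.null(cfg$ja_table)) out$ja_table <- cfg$ja_table
  yaml::write_yaml(out, path)
  invisible(path)
}

fixture_aliases <- c(upper = "upper_limb_analog", lower = "lower_limb_analog",
                     "two-link" = "two_link_arm")

resolve_fixture <- function(cfg) {
  if (is.character(cfg$plant) && cfg$plant %in% names(fixture_aliases))
    cfg$plant <- unname(fixture_aliases[cfg$plant])
  if (is.character(cfg$plant)) {
    if (file.exists(cfg$plant)) {
      plant <- read_plant_yaml(cfg$plant)
      fix <- list(name = cfg$plant, plant = plant,
                  table = make_contribution_table(plant),
                  l0 = equilibrium_lengths(plant))
    } else fix <- build_fixture(cfg$plant)
  } else {
    plant <- plant_from_list(cfg$plant)
    fix <- list(name = "inline", plant = plant,
                table = make_contribution_table(plant),
                l0 = equilibrium_lengths(plant))
  }
  if (!is.null(cfg$ja_table))
    fix$table <- read_contribution_csv(cfg$ja_table,
                                       fix$plant$muscle_names,
                                       fix$plant$joint_names)
  fix
}

write_run_metadata <- function(dir, cfg, extra = list()) {
  meta <- c(list(package_version = as.character(utils::packageVersion("posturerl")),
                 config = list(plant = if (is.character(cfg$plant)) cfg$plant
                               else "inline",
                               fcm = cfg$fcm, ml_sign = cfg$ml_sign,
                               layout = cfg$layout, seed = cfg$seed,
                               learner = unclass(cfg$learner),
                               protocol = unclass(cfg$protocol)[protocol_keys]),
                 provenance = cfg$provenance,
                 stabilization_readout = "mean signed error over final 0.2 s"),
            extra)
  jsonlite::write_json(meta, file.path(dir, "run_metadata.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(meta)
}

run_train_command <- function(cfg) {
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  write_run_metadata(cfg$out_dir, cfg)
  fix <- resolve_fixture(cfg)
  grid <- basis_grid(fix$plant$n_joints, layout = cfg$layout)
  run <- run_training(fix, cfg$fcm, seed = cfg$seed, params = cfg$learner,
                      protocol = cfg$protocol, ml_sign = cfg$ml_sign,
                      grid = grid, record_report = TRUE)
  n_steps <- cfg$protocol$n_steps
  for (key in names(run$report_results)) {
    res <- run$report_results[[key]]
    write_trajectories(seq_len(n_steps) * cfg$protocol$dt, res$angles,
                       res$velocities, fix$plant$joint_names,
                       file.path(cfg$out_dir, paste0("trajectories_trial", key, ".csv")))
    act <- data.frame(time_s = seq_len(n_steps) * cfg$protocol$dt,
                      res$activations, check.names = FALSE)
    utils::write.csv(act, file.path(cfg$out_dir,
                                    paste0("activations_trial", key, ".csv")),
                     row.names = FALSE)
    log <- data.frame(time_s = seq_len(n_steps) * cfg$protocol$dt,
                      reward = res$reward, td_error = res$td_error,
                      value = res$value, noise_scale = res$noise_scale)
    utils::write.csv(log, file.path(cfg$out_dir,
                                    paste0("learning_log_trial", key, ".csv")),
                     row.names = FALSE)
  }
  write_network_json(run$grid, run$critic, run$actor,
                     file.path(cfg$out_dir, "network.json"))
  write_summary(summarize_runs(list(run)),
                file.path(cfg$out_dir, "summary.json"))
  write_summary(summarize_runs(list(run)),
                file.path(cfg$out_dir, "summary.csv"))
  invisible(run)
}

run_predict_command <- function(snapshot, posture_yaml, out_dir, cfg) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_run_metadata(out_dir, cfg, list(snapshot = snapshot,
                                        posture = posture_yaml))
  fix <- resolve_fixture(cfg)
  net <- read_network_json(snapshot)
  posture <- yaml::read_yaml(posture_yaml)
  init <- vapply(fix$plant$joint_names, function(j)
    as.numeric(posture[[j]] %||% fix$plant$targets[[j]]), 0)
  fcm <- fcm_model(cfg$fcm, plant = fix$plant, table = fix$table,
                   ml_sign = cfg$ml_sign)
  res <- predict_posture(fix$plant, net, fcm, init, seed = cfg$seed,
                         params = cfg$learner)
  n_steps <- nrow(res$angles)
  write_trajectories(seq_len(n_steps) * cfg$learner$dt, res$angles,
                     res$velocities, fix$plant$joint_names,
                     file.path(out_dir, "trajectories.csv"))
  act <- data.frame(time_s = seq_len(n_steps) * cfg$learner$dt,
                    res$activations, check.names = FALSE)
  utils::write.csv(act, file.path(out_dir, "activations.csv"),
                   row.names = FALSE)
  invisible(res)
}

#' Command-line entry point
#'
#' Subcommands:
#' * `train --config cfg.yaml [--fcm ml|ja|none] [--fixture NAME]
#'   [--seed S] [--out DIR]` - run a learning experiment; writes
#'   `run_metadata.json`, per-report-trial trajectory and activation CSVs,
#'   the final network snapshot, and the summary table.
#' * `predict --snapshot net.json --posture case.yaml [--config cfg.yaml]
#'   [--out DIR]` - frozen-policy rollout from a fixed posture.
#' * `summarize --out DIR dir1 dir2 ...` - merge summary tables.
#'
#' @param argv Character vector of arguments (default: the command line).
#' @return Integer exit code, invisibly.
#' @export
posturerl_main <- function(argv = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: posturerl <train|predict|summarize> [options]",
    "  train     --config cfg.yaml [--fcm ml|ja|none] [--fixture NAME]",
    "            [--seed S] [--out DIR]",
    "  predict   --snapshot net.json --posture case.yaml",
    "            [--config cfg.yaml] [--out DIR]",
    "  summarize --out DIR dir1 [dir2 ...]", sep = "\n")
  if (!length(argv) || argv[1] %in% c("--help", "-h")) {
    cat(usage, "\n")
    return(invisible(0L))
  }
  cmd <- argv[1]
  rest <- argv[-1]
  opt <- function(flag, default = NULL) {
    i <- which(rest == flag)
    if (length(i)) rest[i[1] + 1] else default
  }
  code <- tryCatch({
    cfg_path <- opt("--config")
    cfg <- if (!is.null(cfg_path)) load_config(cfg_path) else as_run_config()
    if (!is.null(opt("--fcm"))) cfg$fcm <- opt("--fcm")
    if (!is.null(opt("--fixture"))) cfg$plant <- opt("--fixture")
    if (!is.null(opt("--seed"))) cfg$seed <- as.integer(opt("--seed"))
    if (!is.null(opt("--out"))) cfg$out_dir <- opt("--out")
    switch(cmd,
      train = { run_train_command(cfg); 0L },
      predict = {
        snap <- opt("--snapshot"); posture <- opt("--posture")
        if (is.null(snap) || is.null(posture))
          stop2("predict needs --snapshot and --posture")
        run_predict_command(snap, posture, cfg$out_dir, cfg); 0L
      },
      summarize = {
        # positional args = run directories; drop every --flag and its value
        flag_idx <- grep("^--", rest)
        drop <- unique(c(flag_idx, flag_idx + 1))
        dirs <- rest[setdiff(seq_along(rest), drop)]
        missing <- dirs[!dir.exists(dirs)]
        if (length(missing))
          stop2("no such run directory: ", paste(missing, collapse = ", "))
        tabs <- lapply(file.path(dirs, "summary.csv"), read_summary)
        merged <- do.call(rbind, tabs)
        dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
        write_summary(merged, file.path(cfg$out_dir, "summary.csv"))
        write_summary(merged, file.path(cfg$out_dir, "summary.json"))
        0L
      },
      { message("unknown command '", cmd, "'\n", usage); 1L })
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(code)
}
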