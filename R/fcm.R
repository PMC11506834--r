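# Feedback control models: each sets the per-muscle activation CEILING
# u_max that the actor-critic output is then squashed into.
#
#   * fcm_ml  - muscle-length feedback (stretch-reflex analogue)
#   * fcm_ja  - joint-angle feedback through an agonist/synergist
#               contribution table
#   * fcm_none - constant ceiling 1

#' Equilibrium muscle lengths at the neutral posture
#'
#' Computed once as the muscle lengths when every joint sits at its target
#' (neutral body posture) angle. Regenerate whenever the plant geometry or
#' the targets change.
#'
#' @param plant A `posture_plant`.
#' @return Named vector of lengths (m).
#' @export
equilibrium_lengths <- function(plant) muscle_lengths(plant, plant$targets)

#' Muscle-length feedback ceiling
#'
#' As published: `u_max = sig(-500 * dl + 5)` with `dl = (l - l0)/l0`, which
#' assigns a LOWER ceiling to a stretched muscle. The prose account of the
#' same controller describes the opposite slope (a stretched muscle is
#' driven harder, i.e. a stretch reflex), `u_max = sig(+500 * dl + 5)`.
#' Both are available via `ml_sign`; see the package vignette for why the
#' closed-loop experiments use `"narrative"`. At `dl = 0` both give
#' `sig(5) ~= 0.9933`.
#'
#' @param dl Fractional length change(s) from [length_rates()].
#' @param ml_sign `"as_printed"` (default) or `"narrative"`.
#' @return Ceiling(s) in (0, 1).
#' @export
fcm_ml <- function(dl, ml_sign = c("as_printed", "narrative")) {
  ml_sign <- match.arg(ml_sign)
  slope <- if (ml_sign == "as_printed") -500 else 500
  sig(slope * dl + 5)
}

#' Agonist/synergist contribution table
#'
#' Signed percentage contributions `pcm` of each muscle to each controlled
#' joint motion: magnitude 0.5 for agonists, 0.2 for synergists, 0
#' otherwise.
#'
#' @param pcm Numeric matrix, muscles x joint motions, with entries in
#'   `{-0.5, -0.2, 0, 0.2, 0.5}`.
#' @return A `contribution_table`.
#' @export
contribution_table <- function(pcm) {
  ok <- abs(pcm) %in% c(0, 0.2, 0.5)
  if (!all(ok))
    stop2("contribution table entries must be in {-0.5, -0.2, 0, 0.2, 0.5}")
  structure(pcm, class = c("contribution_table", "matrix"))
}

#' Write / read a contribution table as long-format CSV
#'
#' Columns `muscle`, `joint_motion`, `pcm` (nonzero entries only).
#'
#' @param table A [contribution_table()] with dimnames.
#' @param path File path.
#' @param muscles,joints Row/column labels for reading.
#' @return `read_contribution_csv` returns a [contribution_table()].
#' @export
write_contribution_csv <- function(table, path) {
  idx <- which(unclass(table) != 0, arr.ind = TRUE)
  df <- data.frame(muscle = rownames(table)[idx[, 1]],
                   joint_motion = colnames(table)[idx[, 2]],
                   pcm = table[idx])
  utils::write.csv(df[order(df$muscle, df$joint_motion), ], path,
                   row.names = FALSE)
  invisible(path)
}

#' @rdname write_contribution_csv
#' @export
read_contribution_csv <- function(path, muscles, joints) {
  df <- utils::read.csv(path)
  pcm <- matrix(0, length(muscles), length(joints),
                dimnames = list(muscles, joints))
  for (i in seq_len(nrow(df)))
    pcm[df$muscle[i], df$joint_motion[i]] <- df$pcm[i]
  contribution_table(pcm)
}

#' Joint-angle feedback ceiling
#'
#' `u_max_m = sig(sum_jm pcm_mjm * dtheta_jm)` with the angle errors in raw
#' degrees. At the target posture every muscle gets ceiling 0.5. With
#' magnitude-0.5 contributions and errors up to 70 degrees the sigmoid
#' saturates hard, making the ceiling nearly binary away from the target.
#'
#' @param dtheta Angle errors, degrees (clipped state values).
#' @param table A [contribution_table()] (muscles x joints).
#' @return Ceiling per muscle in (0, 1).
#' @export
fcm_ja <- function(dtheta, table) {
  sig(drop(unclass(table) %*% dtheta))
}

#' No feedback control: constant ceiling
#' @param n_muscles Number of muscles.
#' @param u_max_default Ceiling value (default 1).
#' @return Constant vector.
#' @export
fcm_none <- function(n_muscles, u_max_default = 1) {
  rep(u_max_default, n_muscles)
}

#' Bundle a feedback control model choice for the trial runner
#'
#' @param kind `"ml"`, `"ja"` or `"none"`.
#' @param plant A `posture_plant` (used to freeze equilibrium lengths for
#'   `"ml"`; they are computed at the plant's target posture and do NOT
#'   move if the reward targets are later overridden).
#' @param table [contribution_table()] for `"ja"`.
#' @param ml_sign Slope convention for `"ml"`, see [fcm_ml()].
#' @param u_max_default Ceiling for `"none"`.
#' @return An `fcm` object with a `$ceiling(angles, dtheta)` function.
#' @export
fcm_model <- function(kind = c("ml", "ja", "none"), plant = NULL,
                      table = NULL, ml_sign = "as_printed",
                      u_max_default = 1) {
  kind <- match.arg(kind)
  obj <- list(kind = kind, ml_sign = ml_sign)
  if (kind == "ml") {
    if (is.null(plant)) stop2("fcm 'ml' needs a plant")
    l0 <- equilibrium_lengths(plant)
    obj$l0 <- l0
    obj$ceiling <- function(angles, dtheta)
      fcm_ml(length_rates(plant, angles, l0), ml_sign)
  } else if (kind == "ja") {
    if (is.null(table)) stop2("fcm 'ja' needs a contribution table")
    if (is.null(plant)) stop2("fcm 'ja' needs a plant")
    if (nrow(table) != plant$n_muscles)
      stop2("contribution table rows must match the plant's muscles")
    obj$table <- table
    obj$ceiling <- function(angles, dtheta) fcm_ja(dtheta, table)
  } else {
    if (is.null(plant)) stop2("fcm 'none' needs a plant")
    nm <- plant$n_muscles
    obj$ceiling <- function(angles, dtheta) rep(u_max_default, nm)
  }
  structure(obj, class = "fcm")
}
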