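# Musculoskeletal plant: a set of 1-DOF gravity-loaded joint motions
# actuated by muscle action lines with constant moment arms. Joints are
# dynamically independent; muscles couple them only through shared
# activations (bi/multi-articular muscles span several joints).
#
# Conventions (fixed across the package):
#   * public angles/velocities are degrees and degrees/s; dynamics use rad
#   * muscle length l = l_ref - sum_j r_j * (theta_j - theta_ref_j) [rad],
#     so a POSITIVE moment arm shortens the muscle as the angle increases,
#     and muscle tension drives the angle in the shortening direction
#   * gravity torque = -coeff * sin(angle from vertical): a positive
#     coefficient is a restoring (hanging-pendulum) load about 0 degrees

#' Define a joint motion
#'
#' @param name Label for the joint motion.
#' @param angle_range Length-2 numeric, degrees, `c(min, max)`.
#' @param target_angle Target (neutral-posture) angle in degrees; must lie
#'   within `angle_range`.
#' @param inertia Rotational inertia about the axis, kg m^2 (> 0).
#' @param viscous_damping Damping coefficient, N m s/rad (>= 0).
#' @param gravity_torque_coeff Gravity load amplitude, N m. The torque
#'   applied is `-coeff * sin(angle)` with the angle measured from vertical.
#' @param reference_angle Angle (degrees) at which muscle reference lengths
#'   are measured. Defaults to 0.
#' @return A `joint_spec` list.
#' @export
joint_spec <- function(name, angle_range, target_angle, inertia,
                       viscous_damping = 0, gravity_torque_coeff = 0,
                       reference_angle = 0) {
  if (length(angle_range) != 2L || angle_range[1] >= angle_range[2])
    stop2("joint '", name, "': angle_range must be c(min, max) with min < max")
  if (target_angle < angle_range[1] || target_angle > angle_range[2])
    stop2("joint '", name, "': target_angle outside angle_range")
  if (inertia <= 0) stop2("joint '", name, "': inertia must be > 0")
  if (viscous_damping < 0) stop2("joint '", name, "': damping must be >= 0")
  structure(list(name = name, angle_range = as.numeric(angle_range),
                 target_angle = target_angle, inertia = inertia,
                 viscous_damping = viscous_damping,
                 gravity_torque_coeff = gravity_torque_coeff,
                 reference_angle = reference_angle),
            class = "joint_spec")
}

#' Define a muscle action line
#'
#' @param name Label.
#' @param max_force Maximum isometric force, N (> 0). Force is the linear
#'   `u * max_force`; no force-length or force-velocity scaling and no
#'   tendon element.
#' @param reference_length Length (m) when every spanned joint sits at its
#'   `reference_angle`.
#' @param moment_arms Named numeric vector, one signed arm (m) per spanned
#'   joint; zero or absent entries mean the muscle does not span that joint.
#' @return A `muscle_spec` list.
#' @export
muscle_spec <- function(name, max_force, reference_length, moment_arms) {
  if (max_force <= 0) stop2("muscle '", name, "': max_force must be > 0")
  if (reference_length <= 0)
    stop2("muscle '", name, "': reference_length must be > 0")
  if (is.null(names(moment_arms)) || !any(moment_arms != 0))
    stop2("muscle '", name, "': moment_arms must be a named vector with at ",
          "least one nonzero entry")
  structure(list(name = name, max_force = max_force,
                 reference_length = reference_length,
                 moment_arms = moment_arms),
            class = "muscle_spec")
}

#' Assemble a plant from joint and muscle specs
#'
#' Precomputes the dense moment-arm matrix and validates controllability
#' (every joint pulled in both directions) and length positivity over the
#' full admissible angle box.
#'
#' @param joints List of [joint_spec()] objects.
#' @param muscles List of [muscle_spec()] objects.
#' @param gravity_scale Scalar multiplier on all gravity torque
#'   coefficients (1 = configured gravity, 0 = weightless).
#' @param dt Integration step, seconds.
#' @return A `posture_plant` object.
#' @export
plant_config <- function(joints, muscles, gravity_scale = 1, dt = 0.01) {
  jn <- vapply(joints, `[[`, "", "name")
  mn <- vapply(muscles, `[[`, "", "name")
  if (anyDuplicated(jn)) stop2("duplicate joint names")
  if (anyDuplicated(mn)) stop2("duplicate muscle names")
  arms <- matrix(0, length(muscles), length(joints),
                 dimnames = list(mn, jn))
  for (i in seq_along(muscles)) {
    ma <- muscles[[i]]$moment_arms
    unknown <- setdiff(names(ma), jn)
    if (length(unknown))
      stop2("muscle '", mn[i], "' references unknown joint(s): ",
            paste(unknown, collapse = ", "))
    arms[i, names(ma)] <- ma
  }
  plant <- structure(list(
    joints = joints, muscles = muscles,
    joint_names = jn, muscle_names = mn,
    n_joints = length(joints), n_muscles = length(muscles),
    arms = arms,
    range_lo = stats::setNames(vapply(joints, function(j) j$angle_range[1], 0), jn),
    range_hi = stats::setNames(vapply(joints, function(j) j$angle_range[2], 0), jn),
    targets = stats::setNames(vapply(joints, `[[`, 0, "target_angle"), jn),
    inertia = stats::setNames(vapply(joints, `[[`, 0, "inertia"), jn),
    damping = stats::setNames(vapply(joints, `[[`, 0, "viscous_damping"), jn),
    gcoeff = stats::setNames(
      vapply(joints, `[[`, 0, "gravity_torque_coeff") * gravity_scale, jn),
    ref_angles = stats::setNames(vapply(joints, `[[`, 0, "reference_angle"), jn),
    fmax = stats::setNames(vapply(muscles, `[[`, 0, "max_force"), mn),
    lref = stats::setNames(vapply(muscles, `[[`, 0, "reference_length"), mn),
    gravity_scale = gravity_scale, dt = dt), class = "posture_plant")
  validate_plant(plant)
  plant
}

#' Validate a plant configuration
#'
#' Checks that every joint is spanned by at least one muscle pulling in
#' each direction and that every muscle keeps a strictly positive length
#' over the whole admissible angle box (lengths are linear in the angles,
#' so box corners are sufficient).
#'
#' @param plant A `posture_plant`.
#' @return `plant`, invisibly; errors with a named diagnostic otherwise.
#' @export
validate_plant <- function(plant) {
  for (j in seq_len(plant$n_joints)) {
    a <- plant$arms[, j]
    if (!any(a > 0) || !any(a < 0))
      stop2("joint '", plant$joint_names[j], "' is not controllable: needs ",
            "muscles with both positive and negative moment arms")
  }
  # worst-case (shortest) length per muscle over the angle box
  dlo <- deg2rad(plant$range_lo - plant$ref_angles)
  dhi <- deg2rad(plant$range_hi - plant$ref_angles)
  for (m in seq_len(plant$n_muscles)) {
    r <- plant$arms[m, ]
    shortening <- sum(pmax(r * dlo, r * dhi))
    if (plant$lref[m] - shortening <= 0)
      stop2("muscle '", plant$muscle_names[m], "' reaches non-positive ",
            "length within the angle ranges (arms too large)")
  }
  invisible(plant)
}

#' Muscle lengths at a posture
#'
#' Constant-moment-arm linearization: `l = l_ref - sum_j r_j *
#' (theta_j - theta_ref_j)` with the angle difference in radians.
#'
#' @param plant A `posture_plant`.
#' @param angles Joint angles, degrees (plant order).
#' @return Named numeric vector of lengths (m).
#' @export
muscle_lengths <- function(plant, angles) {
  if (any(angles < plant$range_lo - 1e-9) || any(angles > plant$range_hi + 1e-9)) {
    warning("angles outside joint ranges; clamping for length computation")
    angles <- clip(angles, plant$range_lo, plant$range_hi)
  }
  l <- plant$lref - drop(plant$arms %*% deg2rad(angles - plant$ref_angles))
  if (any(l <= 0))
    stop2("non-positive muscle length for '",
          plant$muscle_names[which(l <= 0)[1]], "': configuration error")
  names(l) <- plant$muscle_names
  l
}

#' Fractional muscle length change relative to equilibrium
#'
#' `(l - l0) / l0` per muscle, where `l0` is the equilibrium length at the
#' neutral-posture target angles (see [equilibrium_lengths()]). Zero exactly
#' when all spanned joints sit at their targets.
#'
#' @param plant A `posture_plant`.
#' @param angles Joint angles, degrees.
#' @param l0 Equilibrium lengths; defaults to lengths at the target posture.
#' @return Named dimensionless vector.
#' @export
length_rates <- function(plant, angles, l0 = equilibrium_lengths(plant)) {
  (muscle_lengths(plant, angles) - l0) / l0
}

#' Initial plant state
#'
#' @param plant A `posture_plant`.
#' @param angles Initial joint angles (degrees); default: target posture.
#' @param velocities Initial angular velocities (degrees/s); default 0.
#' @return A `plant_state` list with derived muscle lengths.
#' @export
plant_state <- function(plant, angles = plant$targets,
                        velocities = rep(0, plant$n_joints)) {
  angles <- clip(as.numeric(angles), plant$range_lo, plant$range_hi)
  structure(list(time = 0,
                 angles = stats::setNames(angles, plant$joint_names),
                 velocities = stats::setNames(as.numeric(velocities),
                                              plant$joint_names),
                 muscle_lengths = muscle_lengths(plant, angles)),
            class = "plant_state")
}

#' Advance the plant by one step
#'
#' Torque balance per joint: muscle torques `sum_m r_mj u_m F_max,m`, the
#' gravity load `-coeff * sin(angle)`, and viscous damping. Integrated with
#' semi-implicit Euler (velocity first, then position), which is stable for
#' stiff antagonist co-activation at the default 0.01 s step. Angles are
#' hard-clamped to their ranges with the velocity zeroed at the stop.
#'
#' @param plant A `posture_plant`.
#' @param state A `plant_state`.
#' @param activations Per-muscle activation in \[0, 1\].
#' @param dt Step, seconds (defaults to the plant's configured step).
#' @return The next `plant_state`.
#' @export
plant_step <- function(plant, state, activations, dt = plant$dt) {
  u <- clip(as.numeric(activations), 0, 1)
  tau_m <- drop(crossprod(plant$arms, u * plant$fmax))
  th_rad <- deg2rad(state$angles)
  om_rad <- deg2rad(state$velocities)
  tau <- tau_m - plant$gcoeff * sin(th_rad) - plant$damping * om_rad
  om_rad <- om_rad + dt * tau / plant$inertia
  th_rad <- th_rad + dt * om_rad
  ang <- rad2deg(th_rad)
  vel <- rad2deg(om_rad)
  if (any(!is.finite(ang)) || any(!is.finite(vel)))
    stop2("simulation diverged at joint '",
          plant$joint_names[which(!is.finite(ang) | !is.finite(vel))[1]],
          "' (NaN/Inf state)")
  hit <- ang < plant$range_lo | ang > plant$range_hi
  if (any(hit)) {
    ang <- clip(ang, plant$range_lo, plant$range_hi)
    vel[hit] <- 0
  }
  structure(list(time = state$time + dt,
                 angles = stats::setNames(ang, plant$joint_names),
                 velocities = stats::setNames(as.numeric(vel),
                                              plant$joint_names),
                 muscle_lengths = muscle_lengths(plant, ang)),
            class = "plant_state")
}

#' Write joint trajectories to CSV
#'
#' Columns: `time_s`, one `<joint>_deg` per joint, one `<joint>_degps`
#' per joint, one row per step.
#'
#' @param times Numeric vector of times (s).
#' @param angles Matrix (steps x joints), degrees.
#' @param velocities Matrix (steps x joints), degrees/s.
#' @param joint_names Joint labels.
#' @param path Output file.
#' @export
write_trajectories <- function(times, angles, velocities, joint_names, path) {
  df <- data.frame(time_s = times, angles, velocities, check.names = FALSE)
  names(df) <- c("time_s", paste0(joint_names, "_deg"),
                 paste0(joint_names, "_degps"))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

# ---- YAML serialization ----------------------------------------------------

plant_to_list <- function(plant) {
  list(
    gravity_scale = plant$gravity_scale,
    dt = plant$dt,
    joints = lapply(plant$joints, function(j) {
      list(name = j$name, angle_range = as.numeric(j$angle_range),
           target_angle = j$target_angle, inertia = j$inertia,
           viscous_damping = j$viscous_damping,
           gravity_torque_coeff = j$gravity_torque_coeff,
           reference_angle = j$reference_angle)
    }),
    muscles = lapply(plant$muscles, function(m) {
      list(name = m$name, max_force = m$max_force,
           reference_length = m$reference_length,
           moment_arms = as.list(m$moment_arms))
    }))
}

plant_from_list <- function(x) {
  joints <- lapply(x$joints, function(j)
    joint_spec(j$name, unlist(j$angle_range), j$target_angle, j$inertia,
               j$viscous_damping %||% 0, j$gravity_torque_coeff %||% 0,
               j$reference_angle %||% 0))
  muscles <- lapply(x$muscles, function(m)
    muscle_spec(m$name, m$max_force, m$reference_length,
                unlist(m$moment_arms)))
  plant_config(joints, muscles, gravity_scale = x$gravity_scale %||% 1,
               dt = x$dt %||% 0.01)
}

#' Read / write a plant definition as YAML
#'
#' @param plant A `posture_plant`.
#' @param path File path.
#' @return `read_plant_yaml` returns a `posture_plant`.
#' @export
write_plant_yaml <- function(plant, path) {
  yaml::write_yaml(plant_to_list(plant), path)
  invisible(path)
}

#' @rdname write_plant_yaml
#' @export
read_plant_yaml <- function(path) plant_from_list(yaml::read_yaml(path))

#' @export
print.posture_plant <- function(x, ...) {
  cat("<posture_plant> ", x$n_joints, " joint motions, ", x$n_muscles,
      " muscles\n", sep = "")
  cat("  joints: ", paste(x$joint_names, collapse = ", "), "\n", sep = "")
  biart <- rowSums(x$arms != 0) >= 2
  if (any(biart))
    cat("  multi-articular: ", paste(x$muscle_names[biart], collapse = ", "),
        "\n", sep = "")
  invisible(x)
}
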