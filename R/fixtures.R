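# Desk-scale plant fixtures. These are deliberately small analogs of the
# five controlled joint motions of a right upper / lower extremity: the
# published target (neutral body posture) angles and initial-angle ranges
# are used verbatim, while inertias, damping, gravity loads, maximum
# forces and moment arms are artifact choices (never printed for the
# original model) sized so a passive joint settles in roughly 0.5-1.5 s
# and 2 s episodes can succeed. See the vignette for the sizing rationale.

# shared sizing constants (artifact choices)
FIX_LREF <- 0.30   # m, reference muscle length
FIX_ARM  <- 0.025  # m, principal moment arm

# Dynamics sizing (inertia, damping, gravity, forces) follows the
# operating-point analysis in the vignette: the learner's actor settles
# at a common inhibition of roughly 2*alpha_a*nbar/(alpha_v*kappa) ~ 7.3,
# so the late-learning muscle drive is a few percent of the ceiling and
# gravity loads must stay small against the total muscle torque
# (~150-300x margin), as they are for the heavily over-actuated limbs
# this stands in for.

upper_limb_joints <- function() {
  # name, range lo/hi (printed anatomical ranges), target (printed NBP),
  # inertia, damping, gravity coefficient
  list(
    joint_spec("ELV", c(-135, 17), -88, 0.05, 0.20, 0.025),
    joint_spec("ELW", c(0, 180),     0, 0.05, 0.20, 0.010),
    joint_spec("SHU", c(-120, 40), -39, 0.05, 0.20, 0.010),
    joint_spec("SHV", c(-170, 50), -36, 0.05, 0.20, 0.020),
    joint_spec("SHW", c(-90, 70),   36, 0.05, 0.20, 0.010))
}

lower_limb_joints <- function() {
  # KNW: the printed initial-angle range (-40..10 deg) excludes the
  # printed target (20 deg); the hard range is widened to -40..30 so the
  # target is reachable, the sampling range stays the hard range.
  list(
    joint_spec("KNV", c(-10, 150),  43, 0.10, 0.40, 0.040),
    joint_spec("KNW", c(-40, 30),   20, 0.10, 0.40, 0.015),
    joint_spec("HPU", c(-80, 30),  -12, 0.10, 0.40, 0.015),
    joint_spec("HPV", c(-140, 20), -52, 0.10, 0.40, 0.030),
    joint_spec("HPW", c(-50, 40),   -9, 0.10, 0.40, 0.015))
}

# antagonist pair with equal and opposite arms about one joint
muscle_pair <- function(joint, fmax, arm = FIX_ARM) {
  list(muscle_spec(paste0(joint, "_ag"), fmax, FIX_LREF,
                   stats::setNames(arm, joint)),
       muscle_spec(paste0(joint, "_ant"), fmax, FIX_LREF,
                   stats::setNames(-arm, joint)))
}

build_upper_limb <- function(fmax = 300) {
  joints <- upper_limb_joints()
  jn <- vapply(joints, `[[`, "", "name")
  muscles <- unlist(lapply(jn, muscle_pair, fmax = fmax), recursive = FALSE)
  muscles <- c(muscles, list(
    # biarticular pair spanning elbow and shoulder flexion-extension
    # (biceps/triceps long-head analog)
    muscle_spec("biart_flex", fmax, FIX_LREF,
                c(ELV = 0.020, SHV = 0.015)),
    muscle_spec("biart_ext", fmax, FIX_LREF,
                c(ELV = -0.020, SHV = -0.015)),
    # paired muscles with a secondary motion role (synergists in the
    # joint-angle contribution table); pairing keeps the net torque zero
    # at the neutral posture under uniform co-activation
    muscle_spec("syn_elv_elw_a", fmax, FIX_LREF,
                c(ELV = 0.018, ELW = 0.008)),
    muscle_spec("syn_elv_elw_b", fmax, FIX_LREF,
                c(ELV = -0.018, ELW = -0.008))))
  plant_config(joints, muscles)
}

build_lower_limb <- function(fmax = 500) {
  joints <- lower_limb_joints()
  jn <- vapply(joints, `[[`, "", "name")
  muscles <- unlist(lapply(jn, muscle_pair, fmax = fmax), recursive = FALSE)
  muscles <- c(muscles, list(
    # hamstring / rectus femoris analog: knee flexion-extension coupled
    # to hip flexion-extension
    muscle_spec("biart_post", fmax, FIX_LREF,
                c(KNV = 0.020, HPV = 0.015)),
    muscle_spec("biart_ant", fmax, FIX_LREF,
                c(KNV = -0.020, HPV = -0.015)),
    # biarticular pair across the knee-analog axes
    muscle_spec("biart_kn1", fmax, FIX_LREF,
                c(KNV = 0.015, KNW = 0.010)),
    muscle_spec("biart_kn2", fmax, FIX_LREF,
                c(KNV = -0.015, KNW = -0.010)),
    muscle_spec("syn_hpu_hpw_a", fmax, FIX_LREF,
                c(HPU = 0.018, HPW = 0.008)),
    muscle_spec("syn_hpu_hpw_b", fmax, FIX_LREF,
                c(HPU = -0.018, HPW = -0.008))))
  plant_config(joints, muscles)
}

build_two_link <- function(fmax = 300) {
  joints <- list(
    joint_spec("J1", c(-90, 90), 30, 0.05, 0.20, 0.020),
    joint_spec("J2", c(-120, 60), -45, 0.05, 0.20, 0.015))
  muscles <- c(muscle_pair("J1", fmax), muscle_pair("J2", fmax), list(
    muscle_spec("biart_a", fmax, FIX_LREF, c(J1 = 0.018, J2 = 0.014)),
    muscle_spec("biart_b", fmax, FIX_LREF, c(J1 = -0.018, J2 = -0.014))))
  plant_config(joints, muscles)
}

#' Generate the joint-angle contribution table for a plant
#'
#' Each muscle's primary joint (largest |moment arm|) gets an agonist
#' entry of magnitude 0.5; every other spanned joint gets a synergist
#' entry of magnitude 0.2. Signs follow the restoring convention implied
#' by the plant geometry: a muscle whose tension increases the angle
#' (positive arm) must be recruited when the angle error is negative, so
#' its contribution is `-sign(arm) * magnitude`. The fixed 0.5/0.2
#' magnitudes are applied regardless of the actual arm ratios, mirroring
#' the anatomical-table construction this stands in for.
#'
#' @param plant A `posture_plant`.
#' @return A [contribution_table()] (muscles x joints).
#' @export
make_contribution_table <- function(plant) {
  pcm <- matrix(0, plant$n_muscles, plant$n_joints,
                dimnames = dimnames(plant$arms))
  for (m in seq_len(plant$n_muscles)) {
    r <- plant$arms[m, ]
    spanned <- which(r != 0)
    primary <- spanned[which.max(abs(r[spanned]))]
    for (j in spanned) {
      mag <- if (j == primary) 0.5 else 0.2
      pcm[m, j] <- -sign(r[j]) * mag
    }
  }
  contribution_table(pcm)
}

#' Build a named fixture
#'
#' Catalog:
#' * `"two_link_arm"`: 2 joints, 6 muscles (one antagonist pair per joint
#'   plus a biarticular pair).
#' * `"upper_limb_analog"`: 5 joint motions analog to ELV/ELW/SHU/SHV/SHW
#'   with the published neutral-posture targets (-88, 0, -39, -36, 36)
#'   degrees; 14 muscles including one biarticular pair.
#' * `"lower_limb_analog"`: 5 joint motions analog to KNV/KNW/HPU/HPV/HPW
#'   with targets (43, 20, -12, -52, -9) degrees; 16 muscles including two
#'   biarticular pairs.
#'
#' @param name Fixture name.
#' @param overrides Optional named list merged over the plant definition
#'   (as produced by the YAML serializer) before rebuilding, e.g.
#'   `list(gravity_scale = 0)`.
#' @return List with `plant`, `table` ([contribution_table()]) and `l0`
#'   ([equilibrium_lengths()]).
#' @export
build_fixture <- function(name = c("upper_limb_analog", "lower_limb_analog",
                                   "two_link_arm"),
                          overrides = NULL) {
  name <- match.arg(name)
  plant <- switch(name,
                  upper_limb_analog = build_upper_limb(),
                  lower_limb_analog = build_lower_limb(),
                  two_link_arm = build_two_link())
  if (!is.null(overrides)) {
    lst <- utils::modifyList(plant_to_list(plant), overrides)
    plant <- plant_from_list(lst)
  }
  list(name = name, plant = plant,
       table = make_contribution_table(plant),
       l0 = equilibrium_lengths(plant))
}

#' Random plant for property tests
#'
#' 1-3 joints, an antagonist pair per joint and, with probability 1/2, a
#' biarticular pair across the first two joints. Deterministic given the
#' seed.
#'
#' @param seed Integer seed.
#' @return A `posture_plant`.
#' @export
random_plant <- function(seed) {
  set.seed(seed)
  nj <- sample(1:3, 1)
  joints <- lapply(seq_len(nj), function(j) {
    lo <- stats::runif(1, -150, -20); hi <- stats::runif(1, 20, 150)
    joint_spec(paste0("J", j), c(lo, hi), stats::runif(1, lo / 2, hi / 2),
               inertia = stats::runif(1, 0.02, 0.1),
               viscous_damping = stats::runif(1, 0.1, 0.6),
               gravity_torque_coeff = stats::runif(1, 0, 1.2))
  })
  muscles <- unlist(lapply(seq_len(nj), function(j)
    muscle_pair(paste0("J", j), fmax = stats::runif(1, 80, 300),
                arm = stats::runif(1, 0.015, 0.03))), recursive = FALSE)
  if (nj >= 2 && stats::runif(1) < 0.5) {
    a1 <- stats::runif(1, 0.01, 0.02); a2 <- stats::runif(1, 0.008, 0.018)
    muscles <- c(muscles, list(
      muscle_spec("biart_a", 150, FIX_LREF, c(J1 = a1, J2 = a2)),
      muscle_spec("biart_b", 150, FIX_LREF, c(J1 = -a1, J2 = -a2))))
  }
  plant_config(joints, muscles)
}

#' Jitter a plant's inertias and moment arms
#'
#' Multiplies each inertia and each nonzero arm by an independent factor
#' in `[1 - amount, 1 + amount]`, preserving arm signs (and hence
#' controllability) and re-validating the result.
#'
#' @param plant A `posture_plant`.
#' @param amount Relative jitter, default 0.2. Zero returns the plant
#'   unchanged.
#' @return A perturbed `posture_plant`.
#' @export
perturb_plant <- function(plant, amount = 0.2) {
  if (amount == 0) return(plant)
  joints <- lapply(plant$joints, function(j) {
    j$inertia <- j$inertia * stats::runif(1, 1 - amount, 1 + amount)
    j
  })
  muscles <- lapply(plant$muscles, function(m) {
    m$moment_arms <- m$moment_arms *
      stats::runif(length(m$moment_arms), 1 - amount, 1 + amount)
    m
  })
  plant_config(joints, muscles, gravity_scale = plant$gravity_scale,
               dt = plant$dt)
}
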