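# Normalized Gaussian network shared by critic and actor.
#
# The state is the concatenated (angle error, velocity error) of the
# controlled joint motions, clipped to a fixed box. Basis function i is a
# Gaussian in that space, normalized across the K functions so the vector
# b(s) is a partition of unity; critic value and per-muscle actor actions
# are linear in b.

STATE_ANGLE_CLIP <- 70    # degrees
STATE_VEL_CLIP   <- 300   # degrees/s

#' Build the controlled-subspace state vector
#'
#' Per controlled joint motion: `dtheta = angle - target` clipped to
#' \[-70, 70\] degrees and `dthetadot = velocity` (target velocity zero)
#' clipped to \[-300, 300\] degrees/s.
#'
#' @param angles,velocities Degrees and degrees/s, one per controlled joint.
#' @param targets Target angles, degrees.
#' @return Numeric vector `c(dtheta, dthetadot)` of length `2 * n_joints`.
#' @export
make_state <- function(angles, velocities, targets) {
  c(clip(angles - targets, -STATE_ANGLE_CLIP, STATE_ANGLE_CLIP),
    clip(velocities, -STATE_VEL_CLIP, STATE_VEL_CLIP))
}

#' Construct the basis-function grid
#'
#' Centers lie on a uniform `n_angle x n_vel` lattice over the clipped
#' (dtheta, dthetadot) box. Two layouts are available:
#'
#' * `"shared"` (default): one K-center grid whose (angle, velocity)
#'   coordinates are replicated across every controlled joint motion's
#'   plane; basis i is the product of identical per-joint Gaussian factors.
#'   K = n_angle * n_vel (144 with the defaults).
#' * `"tiled"`: an independent lattice per joint motion; basis functions
#'   respond to a single joint's (dtheta, dthetadot) only, and
#'   K = n_joints * n_angle * n_vel.
#'
#' Widths default to 26.5 degrees (angle axes) and 163.6 degrees/s
#' (velocity axes).
#'
#' @param n_joints Number of controlled joint motions.
#' @param n_angle,n_vel Lattice points per axis.
#' @param sigma_angle,sigma_vel Gaussian widths.
#' @param layout `"shared"` or `"tiled"`.
#' @return A `basis_grid` object with `K` basis functions.
#' @export
basis_grid <- function(n_joints, n_angle = 12, n_vel = 12,
                       sigma_angle = 26.5, sigma_vel = 163.6,
                       layout = c("shared", "tiled")) {
  layout <- match.arg(layout)
  stopifnot(sigma_angle > 0, sigma_vel > 0, n_angle >= 1, n_vel >= 1)
  ca <- seq(-STATE_ANGLE_CLIP, STATE_ANGLE_CLIP, length.out = n_angle)
  cv <- seq(-STATE_VEL_CLIP, STATE_VEL_CLIP, length.out = n_vel)
  lattice <- as.matrix(expand.grid(angle = ca, vel = cv))
  K <- if (layout == "shared") nrow(lattice) else n_joints * nrow(lattice)
  structure(list(n_joints = n_joints, layout = layout,
                 lattice = lattice, K = K,
                 sigma_angle = sigma_angle, sigma_vel = sigma_vel,
                 n_angle = n_angle, n_vel = n_vel),
            class = "basis_grid")
}

#' Evaluate the normalized basis vector
#'
#' Unnormalized `B_i = exp(-sum_k ((s_k - c_ik) / sigma_k)^2)`; the
#' returned `b_i = B_i / sum_l B_l`. Evaluated in the log domain
#' (max-subtracted), so far-from-support states degrade gracefully to a
#' nearest-center one-hot instead of underflowing to 0/0.
#'
#' @param grid A `basis_grid`.
#' @param s State vector from [make_state()].
#' @return Numeric vector of length `grid$K`; nonnegative, sums to 1.
#' @export
ngn_basis <- function(grid, s) {
  nj <- grid$n_joints
  dth <- s[seq_len(nj)]
  dthd <- s[nj + seq_len(nj)]
  la <- grid$lattice[, 1]
  lv <- grid$lattice[, 2]
  if (grid$layout == "shared") {
    # per lattice point: sum over joints of the two squared distances
    logB <- -(outer(la, dth, function(c, x) ((x - c) / grid$sigma_angle)^2) %*%
                rep(1, nj) +
              outer(lv, dthd, function(c, x) ((x - c) / grid$sigma_vel)^2) %*%
                rep(1, nj))
  } else {
    # one lattice per joint; each basis sees only its joint's plane
    logB <- -as.vector(vapply(seq_len(nj), function(j)
      ((dth[j] - la) / grid$sigma_angle)^2 +
      ((dthd[j] - lv) / grid$sigma_vel)^2, numeric(nrow(grid$lattice))))
  }
  logB <- logB - max(logB)
  B <- exp(logB)
  drop(B / sum(B))
}

#' Critic: linear state-value function on the basis
#'
#' Weights initialize to zero so the value surface (and hence the
#' exploration noise scale) is exactly reproducible at trial 1.
#'
#' @param grid A `basis_grid`.
#' @return A `critic` object with zero weights `v`.
#' @export
critic_new <- function(grid) {
  structure(list(v = numeric(grid$K)), class = "critic")
}

#' Actor: per-muscle linear action functions on the basis
#'
#' @param grid A `basis_grid`.
#' @param n_muscles Number of muscles.
#' @return An `actor` object with a zero `K x n_muscles` weight matrix `w`.
#' @export
actor_new <- function(grid, n_muscles) {
  structure(list(w = matrix(0, grid$K, n_muscles)), class = "actor")
}

#' Critic value `V(s) = sum_i v_i b_i(s)`
#' @param critic A `critic`.
#' @param b Basis vector from [ngn_basis()].
#' @return Scalar value.
#' @export
ngn_value <- function(critic, b) sum(critic$v * b)

#' Actor actions `a_m(s) = sum_i w_im b_i(s)`
#' @param actor An `actor`.
#' @param b Basis vector.
#' @return Numeric vector, one action per muscle.
#' @export
ngn_action <- function(actor, b) drop(crossprod(actor$w, b))

# ---- snapshot serialization ------------------------------------------------

#' Save / load a network snapshot (grid + critic + actor weights) as JSON
#'
#' Round-trip lossless: weights are written at full double precision.
#'
#' @param grid A `basis_grid`.
#' @param critic A `critic`.
#' @param actor An `actor`.
#' @param path File path.
#' @return `read_network_json` returns `list(grid, critic, actor)`.
#' @export
write_network_json <- function(grid, critic, actor, path) {
  obj <- list(grid = list(n_joints = grid$n_joints, layout = grid$layout,
                          n_angle = grid$n_angle, n_vel = grid$n_vel,
                          sigma_angle = grid$sigma_angle,
                          sigma_vel = grid$sigma_vel),
              v = critic$v, w = actor$w)
  # I(17) significant digits: doubles survive the decimal round trip exactly
  jsonlite::write_json(obj, path, digits = I(17), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_network_json
#' @export
read_network_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  g <- obj$grid
  grid <- basis_grid(g$n_joints, g$n_angle, g$n_vel, g$sigma_angle,
                     g$sigma_vel, g$layout)
  critic <- critic_new(grid)
  critic$v <- as.numeric(obj$v)
  actor <- actor_new(grid, ncol(obj$w))
  actor$w <- matrix(as.numeric(obj$w), grid$K)
  list(grid = grid, critic = critic, actor = actor)
}
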