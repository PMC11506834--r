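# Continuous-time actor-critic learning step, Euler-discretized at the
# plant step dt. All defaults are the published operating point of the
# controller; gamma is fully determined as (1 - dt/tau) and is not a free
# parameter.

#' Learner hyperparameters
#'
#' Defaults: critic rate `alpha_v = 0.3`, actor rate `alpha_a = 0.11`,
#' value time constant `tau = 0.05` s, trace time constant `kappa = 0.05` s,
#' activation cost weight `c = 0.01`, reward width `sigma_r = 100`
#' (degrees and degrees/s), sigmoid constants `A = 1`, `B = -4`, default
#' activation ceiling `u_max_default = 1`, step `dt = 0.01` s. With these,
#' both the TD discount `(1 - dt/tau)` and the per-step trace decay
#' `(1 - dt/kappa)` equal 0.8.
#'
#' @param alpha_v,alpha_a Learning rates.
#' @param tau,kappa Time constants, s; both must exceed `dt`.
#' @param c Activation cost weight.
#' @param sigma_r Reward kernel width.
#' @param A,B Activation sigmoid constants.
#' @param u_max_default Ceiling used when no feedback control model is active.
#' @param dt Step, s.
#' @return A `learner_params` list.
#' @export
learner_params <- function(alpha_v = 0.3, alpha_a = 0.11, tau = 0.05,
                           kappa = 0.05, c = 0.01, sigma_r = 100,
                           A = 1, B = -4, u_max_default = 1, dt = 0.01) {
  stopifnot(tau > dt, dt > 0, kappa > 0, sigma_r > 0)
  structure(list(alpha_v = alpha_v, alpha_a = alpha_a, tau = tau,
                 kappa = kappa, c = c, sigma_r = sigma_r, A = A, B = B,
                 u_max_default = u_max_default, dt = dt),
            class = "learner_params")
}

#' Reward
#'
#' `r = sum_i [exp(-(dtheta_i/sigma_r)^2) + exp(-(dthetadot_i/sigma_r)^2)]
#' - c * sum_m u_m^2` over the controlled joint motions and all muscles.
#' Bounded in `(-c*N, 2*n_joints]`; the maximum `2 * n_joints` is attained
#' at zero error with zero activation.
#'
#' @param s State vector from [make_state()] (already clipped).
#' @param u Muscle activations.
#' @param p [learner_params()].
#' @return Scalar reward.
#' @export
acrl_reward <- function(s, u, p) {
  nj <- length(s) / 2
  dth <- s[seq_len(nj)]
  dthd <- s[nj + seq_len(nj)]
  sum(exp(-(dth / p$sigma_r)^2) + exp(-(dthd / p$sigma_r)^2)) -
    p$c * sum(u^2)
}

#' Temporal-difference error
#'
#' `delta = r + (1 - dt/tau) * V_next - V`. The discount is exactly 0.8 at
#' the default operating point.
#'
#' @param r Reward.
#' @param v_t,v_next Critic values at the current and next state.
#' @param p [learner_params()].
#' @return Scalar TD error.
#' @export
td_error <- function(r, v_t, v_next, p) {
  r + (1 - p$dt / p$tau) * v_next - v_t
}

#' Eligibility-trace update
#'
#' Euler step of `de/dt = -e/kappa + dV/dv_k` with `dV/dv_k = b_k`:
#' `e <- (1 - dt/kappa) * e + dt * b`. Traces are reset to zero at the
#' start of every trial (episodes are independent).
#'
#' @param e Trace vector (length K).
#' @param b Basis vector at the current state.
#' @param p [learner_params()].
#' @return Updated trace vector.
#' @export
update_traces <- function(e, b, p) {
  (1 - p$dt / p$kappa) * e + p$dt * b
}

#' Critic weight update `v_i <- v_i + alpha_v * delta * e_i`
#' @param critic A `critic`.
#' @param delta TD error.
#' @param e Eligibility traces.
#' @param p [learner_params()].
#' @return Updated critic.
#' @export
update_critic <- function(critic, delta, e, p) {
  critic$v <- critic$v + p$alpha_v * delta * e
  critic
}

#' Actor weight update
#'
#' `w_im <- w_im + alpha_a * delta * n_m * exp(-0.5 V) * b_i`: the
#' exploration noise that perturbed muscle m is credited (or blamed) in
#' proportion to the TD error, attenuated as the learned value grows.
#'
#' @param actor An `actor`.
#' @param delta TD error.
#' @param n Per-muscle noise drawn this step.
#' @param V Critic value at the current state.
#' @param b Basis vector at the current state.
#' @param p [learner_params()].
#' @return Updated actor.
#' @export
update_actor <- function(actor, delta, n, V, b, p) {
  scale <- p$alpha_a * delta * exp(-0.5 * V)
  if (scale != 0) actor$w <- actor$w + scale * outer(b, n)
  actor
}

#' Muscle activation
#'
#' `u_m = u_max_m * sig(-A * (a_m + exp(-0.5 V) * n_m) - B)`. With the
#' defaults `A = 1, B = -4` this is `u_max * sig(4 - a - sigma*n)`: note
#' the printed leading minus sign, under which a LARGER actor output
#' INHIBITS the muscle. The learning rule in [update_actor()] shares that
#' sign, so credit assignment stays consistent; the convention is kept
#' exactly as published.
#'
#' @param a Actor outputs, one per muscle.
#' @param V Critic value (sets the noise scale `exp(-0.5 V)`).
#' @param n Per-muscle noise in \[0, 1\].
#' @param u_max Per-muscle ceilings from the active feedback control model.
#' @param p [learner_params()].
#' @return Activations in `(0, u_max)` elementwise (0 where `u_max` is 0).
#' @export
activation <- function(a, V, n, u_max, p) {
  u_max * sig(-p$A * (a + exp(-0.5 * V) * n) - p$B)
}

#' Exploration noise: independent uniform draws on \[0, 1\], one per muscle
#'
#' Uniform (not zero-mean) as published; the activation map turns it into
#' a one-sided inhibitory perturbation whose scale shrinks as the value
#' function grows.
#'
#' @param n_muscles Number of draws.
#' @return Numeric vector in \[0, 1\].
#' @export
acrl_noise <- function(n_muscles) stats::runif(n_muscles)
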