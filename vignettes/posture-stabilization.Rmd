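---
title: "Involuntary posture stabilization: model, assumptions, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Involuntary posture stabilization: model, assumptions, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`posturerl` simulates how a redundant set of muscles can stabilize a limb
posture under gravity *involuntarily*: a reinforcement learner provides slow,
value-guided adaptation, while a fast feedback law — driven by each muscle's
own length change, a stretch-reflex analogue — supplies most of the
stabilizing action from the first trial. This vignette documents the model,
every tunable that matters, what the desk-scale fixtures do and do not
emulate, and the design choices made where the published description is
silent or self-contradictory.

## 1. The plant

Each *joint motion* is a 1-DOF rotational state $(\theta_j,\dot\theta_j)$
(degrees, degrees/s at the interface; radians internally) obeying

$$ I_j\ddot\theta_j \;=\; \sum_m r_{mj}\,u_m F_{\max,m}
   \;-\; G_j\sin\theta_j \;-\; D_j\dot\theta_j , $$

integrated by semi-implicit Euler at $\Delta t = 0.01$ s. Muscle force is
linear in activation ($F = uF_{\max}$): no force–length or force–velocity
scaling, no activation lag, and no tendon element. Muscle geometry is the
constant-moment-arm linearization

$$ l_m \;=\; l_{\mathrm{ref},m} - \sum_j r_{mj}\,(\theta_j-\theta_{\mathrm{ref},j}), $$

so a muscle with a positive arm shortens as its joint angle increases, and
its tension drives the angle in the shortening direction. A muscle with two
or more nonzero arms is biarticular. Angles hard-clamp at their anatomical
ranges with the velocity zeroed at the stop.

## 2. The controller

**State.** Per controlled joint motion, the angle error
$d\theta = \theta - \theta^{\mathrm{trg}}$ clipped to $[-70, 70]$ degrees and
the velocity error $d\dot\theta$ clipped to $[-300, 300]$ degrees/s. Target
velocities are zero.

**Function approximator.** A normalized Gaussian network: Gaussian bumps
$B_i(s)$ with widths 26.5 degrees (angle axes) and 163.6 degrees/s (velocity
axes), normalized to a partition of unity $b_i = B_i / \sum_l B_l$ (evaluated
in the log domain, so far-from-support states degrade to a nearest-center
one-hot instead of 0/0). Critic value $V = \sum_i v_i b_i$ and per-muscle
actions $a_m = \sum_i w_{im} b_i$; all weights start at zero, which makes
trial 1 exactly reproducible.

**Learning step** (per 0.01 s, the standard continuous-time actor–critic
sequence): observe $s(t)$; compute $V$, $a$, the ceiling $u^{\max}$, draw
per-muscle uniform noise $n_m \in [0,1]$; set the activation

$$ u_m = u_m^{\max}\,\mathrm{sig}\!\big(-A(a_m + e^{-V/2} n_m) - B\big),
   \qquad A = 1,\; B = -4, $$

advance the plant; reward
$r = \sum_i [e^{-(d\theta_i/\sigma_r)^2} + e^{-(d\dot\theta_i/\sigma_r)^2}]
- c\sum_m u_m^2$ with $\sigma_r = 100$, $c = 0.01$; TD error
$\delta = r + (1-\Delta t/\tau)V(s') - V(s)$ with $\tau = 0.05$ s (discount
exactly 0.8); eligibility traces
$e \leftarrow (1-\Delta t/\kappa)e + \Delta t\, b$ with $\kappa = 0.05$ s;
critic $v_i \mathrel{+}= \alpha_V\,\delta\,e_i$ ($\alpha_V = 0.3$) and actor
$w_{im} \mathrel{+}= \alpha_a\,\delta\,n_m\,e^{-V/2}\,b_i$
($\alpha_a = 0.11$). Traces reset at each trial start; weights persist.

Note the sign structure: with the standard logistic `sig`, a larger actor
output *inhibits* its muscle, and the update reinforces whatever the
(one-sided, inhibitory) noise did when $\delta > 0$. The two minus signs are
consistent with each other and are implemented exactly as published.

**Feedback control models** set each muscle's ceiling $u^{\max}_m$:

* `ml` — muscle length: $u^{\max} = \mathrm{sig}(\mp 500\,\Delta l + 5)$
  with $\Delta l = (l - l_0)/l_0$ and $l_0$ the length at the neutral body
  posture (NBP). See Section 4 below on the sign.
* `ja` — joint angle: $u^{\max} = \mathrm{sig}(\sum_{jm} pc_{m,jm}\,
  d\theta_{jm})$ with signed contributions $\pm 0.5$ (agonists) and
  $\pm 0.2$ (synergists), angle errors in raw degrees.
* `none` — constant 1.

## 3. Protocols

A *trial* is a 2.0 s episode (200 steps) from initial angles drawn uniformly
from each joint's anatomical range; a *training run* is 300 sequential
trials with persistent weights, scored at trials 1, 2, 3, 20, 300 by the
number of joint motions whose final error lies within $\pm 5$ degrees. The
readout is the mean signed error over the final 0.2 s (20 samples),
inclusive at exactly 5 degrees — a windowed mean rather than a single
possibly-noisy last sample; this choice is recorded in every run's metadata.
*Posture-change predictions* freeze the trained weights (noise stays active
at scale $e^{-V/2}$) and roll out 2.0 s from fixed initial postures.

Each run derives independent seed streams for initial angles and for
exploration noise, so retaining or dropping diagnostics never shifts a
trajectory.

## 4. Where the published description is ambiguous, and what we chose

**The muscle-length sign.** Taken literally (standard logistic), the printed
ceiling $\mathrm{sig}(-500\Delta l + 5)$ gives a *shortened* muscle the
higher ceiling. Because muscle tension acts in the shortening direction,
that is positive feedback: in our plants every joint is driven into its
range stop and zero joint motions stabilize (verified over full 300-trial
runs). The same work's prose describes the opposite — stretch *enhances*
activation, extensors of an over-flexed joint pull it back — which is the
classical stretch reflex and is what its reported results require. Both
slopes are implemented (`ml_sign = "as_printed"` / `"narrative"`); the
static closed forms default to the printed slope, while the closed-loop
experiments use `"narrative"`. Neither is endorsed as "what the equation
meant"; the discrepancy is documented, not resolved.

**Basis layout.** The published configuration (144 centers over a
112-dimensional state) cannot tile per joint motion, so its centers cover
the state space jointly. Replicating one 12x12 (angle x velocity) lattice
across all controlled joints (`layout = "shared"`, K = 144) makes the basis
*permutation-invariant across joints*: the network can represent "some joint
is 20 degrees off" but not *which* — and measured stabilization saturates at
2–4 of 5. The `"tiled"` layout (an independent 12x12 plane per joint,
K = 720) restores joint identity; with it the actor learns joint-specific
gravity compensation and braking, and the comparative results reproduce.
`basis_grid()` defaults to the published shared grid; the experiment layer
defaults to tiled. This is the one place we depart from a literal scaled
replica to recover the published behavior, and it is a representational
necessity, not a tuning choice.

**The learner's operating point (why fixtures are sized the way they are).**
The exploration noise is uniform on $[0,1]$ — not zero-mean. Early in
learning $\delta \approx r \approx 10$ for many steps (the critic must build
$V$ up to its fixed point $V^\ast = r/(1 - 0.8) \approx 50$ through
eligibility traces of stationary magnitude $\kappa b$), and during that
transient *every* actor weight drifts upward at rate
$\alpha_a \bar n \delta e^{-V/2}$ against a critic rate $\alpha_V \kappa
\delta$, integrating to a common inhibition of
$a_\infty \approx 2\alpha_a \bar n / (\alpha_V \kappa) \approx 7.3$
before $e^{-V/2}$ freezes all learning. The learned controller therefore
operates at $u \approx \mathrm{sig}(4 - a_\infty) \approx 1.5\text{–}3\%$ of
its ceiling (measured: mean $u = 0.015$–$0.03$). This is a structural
consequence of the published constants. It dictates the fixture sizing:
gravity torques must be small against total muscle torque
($\sim 1/150$, as they are for real, heavily over-actuated limbs), and
damping must trade early-trial relay stability against the late-phase
low-drive crawl. We size inertias at 0.05–0.1 kg m^2, damping 0.2–0.4
N m s/rad, gravity coefficients 0.01–0.04 N m and forces 300–500 N, chosen
once by this analysis plus one damping comparison, then frozen. A
consequence accepted knowingly: a *passive* fixture limb settles on a
gravity timescale of seconds, not the ~1 s a naive sizing would target —
closed-loop stabilizability at the published operating point won.

**Other choices.** `sig` is the standard logistic (never defined in the
source description; all closed-form anchors assume it). The TD discount is
fully determined as $1-\Delta t/\tau$; no separate parameter exists. Traces
reset at trial starts because trials are independent episodes. The
knee-rotation analog's hard range is widened to (−40, 30) degrees because
the published initial range (−40, 10) excludes the published target (20) —
a plant clamped at 10 could never satisfy it.

## 5. What the fixtures emulate — and what they do not

`upper_limb_analog` (5 joint motions, 14 muscles) and `lower_limb_analog`
(5 joint motions, 16 muscles, two biarticular pairs) reuse the published NBP
targets and anatomical ranges verbatim; muscle counts, arms and dynamics are
desk-scale stand-ins for a 949-muscle anthropometric model that is out of
scope. Every antagonist is paired with equal-and-opposite arms, so uniform
co-activation is torque-free at the NBP — the real anatomical property that
makes "activate everything near its ceiling" a viable resting strategy.

A green comparative test here establishes that the *control architecture*
(length-change ceilings + value-guided actor on a normalized Gaussian
network) stabilizes a redundant, gravity-loaded, biarticularly-coupled
plant at the published hyperparameters, and that removing the feedback
destroys it. It does **not** establish anatomical fidelity, and two of the
published contrasts do not transfer down in scale:

* **Joint-angle feedback does not fail here.** Our contribution tables are
  generated from the fixture's own moment arms, so sign and role are always
  mechanically consistent, and the joint-angle model stabilizes 5/5. The
  published failure of that model is attributed to fixed anatomical
  contributions that are wrong for most of 56 joint motions; a 5-joint
  analog whose muscle "roles" are *defined* by its arms has no non-arbitrary
  way to reproduce that misassignment, and we declined to sabotage the
  table to force the headline result. The corresponding acceptance
  assertion is intentionally left failing.
* **Learning does not visibly improve across trials.** At this scale the
  length-feedback alone already stabilizes 5/5 at trial 1 (the original
  reports 3), so the late-vs-early error contrast has no headroom; indeed
  the actor's structural drift *slightly degrades* precision (mean absolute
  final error grows from ~1.6 to ~2.4 degrees). That acceptance assertion
  is also left failing, with this explanation.

## 6. Numerical notes

Basis evaluation is log-domain (max-subtracted) — partition of unity holds
to 1e-12 everywhere representable. Network snapshots serialize weights with
17 significant digits, which round-trips doubles exactly. The integrator is
deterministic; identical seeds give bit-identical runs (asserted). Divergent
dynamics (NaN/Inf) abort a trial, which scores zero. Degenerate inputs —
uncontrollable joints, slack muscles anywhere in the angle box, malformed
configs — are rejected at construction with named diagnostics.

## 7. Known limitations

No tendon or Hill-type muscle dynamics (stated as future work in the source
description); no deep-network (DDPG) comparison arm; no anatomical moment-arm
validation; contribution tables are labeled analogs, never claimed to equal
the published appendix tables. The two intentionally-red acceptance
assertions above are the honest boundary of what a desk-scale analog can
reproduce.
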