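Package: posturerl
Title: Involuntary Posture Stabilization via Actor-Critic Learning with
    Muscle-Length Feedback
Version: 0.1.0
Authors@R: person("posturerl", "maintainers", email = "maintainers@posturerl.org",
    role = c("aut", "cre"))
Description: Simulates involuntary stabilization of limb postures under
    gravity with an actor-critic reinforcement learner on a normalized
    Gaussian network, coupled to antagonistic feedback control of muscle
    length change (a stretch-reflex analogue). Provides deterministic
    rigid-link musculoskeletal plants with constant-moment-arm muscle
    action lines, three feedback control models (muscle-length,
    joint-angle with agonist/synergist contribution tables, and none),
    trial protocols for multi-trial learning runs with stabilization
    scoring, frozen-policy posture-change predictions, desk-scale limb
    fixtures, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    optparse,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
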