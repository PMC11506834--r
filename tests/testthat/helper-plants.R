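# Tiny plants built in code for unit tests.

# single hanging pendulum joint with an antagonist muscle pair
pendulum_plant <- function(inertia = 0.05, damping = 0, gravity = 0.5,
                           arm = 0.02, fmax = 100) {
  plant_config(
    list(joint_spec("J1", c(-170, 170), 0, inertia, damping, gravity)),
    list(muscle_spec("flex", fmax, 0.3, c(J1 = arm)),
         muscle_spec("ext", fmax, 0.3, c(J1 = -arm))))
}

# two joints, one biarticular pair on top of per-joint pairs
two_joint_plant <- function() {
  plant_config(
    list(joint_spec("J1", c(-90, 90), 20, 0.05, 0.2, 0.02),
         joint_spec("J2", c(-120, 60), -40, 0.05, 0.2, 0.015)),
    list(muscle_spec("f1", 100, 0.3, c(J1 = 0.02)),
         muscle_spec("e1", 100, 0.3, c(J1 = -0.02)),
         muscle_spec("f2", 100, 0.3, c(J2 = 0.02)),
         muscle_spec("e2", 100, 0.3, c(J2 = -0.02)),
         muscle_spec("bi_a", 100, 0.3, c(J1 = 0.03, J2 = -0.02)),
         muscle_spec("bi_b", 100, 0.3, c(J1 = -0.03, J2 = 0.02))))
}
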