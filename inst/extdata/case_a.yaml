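# Posture-change case A analog: shoulder forward flexion at -90 deg,
# elbow extended. Joints omitted here default to their target angles.
ELV: 0
ELW: 0
SHU: 0
SHV: -90
SHW: 0
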