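# Posture-change case C analog: shoulder external rotation 90 deg (clamps
# to the SHU range maximum of 40 deg on this plant), elbow flexed -90 deg.
ELV: -90
ELW: 0
SHU: 90
SHV: 0
SHW: 0
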