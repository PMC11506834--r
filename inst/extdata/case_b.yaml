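# Posture-change case B analog: backward shoulder extension 40 deg,
# elbow inversion 60 deg.
ELV: 0
ELW: 60
SHU: 0
SHV: 40
SHW: 0
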