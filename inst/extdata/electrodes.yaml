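# Electrode geometry registry. Offsets are contact-center distances from the
# lead tip along the shaft (mm). Segmented contacts carry the base angle of
# their segment (degrees); the lead rotation is added on top.
medtronic-3389:
  description: 4 omnidirectional ring contacts (1.5 mm length, 0.5 mm gaps)
  contacts:
    - {offset: 0.75, kind: omni}
    - {offset: 2.75, kind: omni}
    - {offset: 4.75, kind: omni}
    - {offset: 6.75, kind: omni}
bsc-vercise-cartesia:
  description: Directional 1-3-3-1 lead (tip ring, two segmented levels, top ring)
  contacts:
    - {offset: 0.75, kind: omni}
    - {offset: 2.75, kind: segment, angle: 0}
    - {offset: 2.75, kind: segment, angle: 120}
    - {offset: 2.75, kind: segment, angle: 240}
    - {offset: 4.75, kind: segment, angle: 0}
    - {offset: 4.75, kind: segment, angle: 120}
    - {offset: 4.75, kind: segment, angle: 240}
    - {offset: 6.75, kind: omni}
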