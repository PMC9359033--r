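# Validation geometry: closed-form benchmark leaf.
sad_cm: 100.00
scd_cm: 51.0
height_cm: 6.13
tip_radius_cm: 8.00
body_length_cm: 15
hvl_cm: 0.950
bank: right
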