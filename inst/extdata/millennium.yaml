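# Millennium-like leaf: 8.0 cm tip radius with the HDMLC height,
# transmission and machine geometry.
sad_cm: 100.00
scd_cm: 51.0
height_cm: 6.60
tip_radius_cm: 8.0
body_length_cm: 15
transmission: 0.0122
bank: right
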