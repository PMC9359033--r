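# Varian high-definition MLC leaf, flattened 6 MV beam.
# SCD references the proximal (top) leaf surface.
sad_cm: 100.00
scd_cm: 51.0
height_cm: 6.60
tip_radius_cm: 16.00
body_length_cm: 15
transmission: 0.0122
bank: right
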