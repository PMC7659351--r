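# Jaszczak-like hot-rod phantom: 19 rods (9 x 15.4 mm, 6 x 19.1 mm,
# 4 x 25.4 mm) in a cold 25.6 cm boundary.
preset: jaszczak
activity_mci: 2
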