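# 30 cm contrast phantom: 10 cm hot and cold rods in a warm background,
# activity concentrations hot:background:cold = 2:1:0.
preset: contrast
activity_mci: 2
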