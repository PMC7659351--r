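# 2 mCi point source at the center of the field of view.
preset: point
activity_mci: 2
position: [0, 0, 0]
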