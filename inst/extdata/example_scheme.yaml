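# Quarter-half-quarter regional division of the antero-posterior width.
boundaries: [0.25, 0.75]
labels: [anterior, middle, posterior]
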