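x_min: 0
y_min: 0
x_max: 400
y_max: 500
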