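grade,cw_low,cw_high,bf_low,bf_high
1+,83,93,17,25
1,80,98,15,28
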