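component,eigenvalue,pct_variance
1,6.39,45.64
2,1.88,13.41
3,1.18,8.45
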