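year,n_pairs
2014,29
2015,23
2016,21
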