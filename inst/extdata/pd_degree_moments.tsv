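network	mean_degree	sd_degree
ttest	3.4	4.2
sam	2.8	2.9
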