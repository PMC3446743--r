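cluster	n_catalogues	n_tags
C	185	13165432
N	166	12953131
IV	112	8009673
D	29	1840291
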