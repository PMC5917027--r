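mt_synthetic	15000	16200	dloop_synthetic
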