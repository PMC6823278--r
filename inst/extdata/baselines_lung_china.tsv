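stratum	p0
men	0.0562
women	0.0256
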