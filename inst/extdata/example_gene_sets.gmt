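migs	synthetic example set	RNPC3	BRAF	SPC24	CACNA1D	VEZT
kinome	synthetic example set	BRAF	MAP2K1	MAP2K2	CDK1
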