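region	A	T	G	C
5LR	32.01	32.68	16.45	18.86
3PT	21.12	46.95	8.66	23.27
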