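CHR	POS	EA	OA	BETA	SE	P	EAF
1	12345	A	G	0.182321557	0.031	4.2e-09	0.41
2	67890	T	C	-0.051293294	0.012	0.0021	0.18
11	2847895	C	A	0.27	0.045	1.8e-09	0.49
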