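subsite	A	C	D	E	F	G	H	I	K	L	M	N	P	Q	R	S	T	V	W	Y
P4	0	0	0	0	0	0	0	0	0.842	0	0	0	0	0	0	0	0	0	0	0
P3	0	0	0	0	0	0.3	0	0	0	0	0	-0.3	0	0	0	0	0	0	0	0
P2	0	0	0	0	0.5	0.5	0	0	0.8	0.8	0	0.858	0.3	0	1	0	0	0	0	0
P1	0	0	0	0	0	1.058	0	0	1.2	0	0	0.8	0	0	1.867	0	0.3	0	0	0
P1'	0	0	0	0	0	0.842	0	0	0.383	0.5	0	0	0.3	-0.083	0	0	0	0	0	0.3
P2'	0	0	0	0	0	0.042	0	0	0	0	0	0	0	0	-0.333	0	0	0	0	0
P3'	0	0	0	0	0	0	0	0	-0.142	0	0	0	0	0	0	0	0	0	0	0
P4'	0	0	0	0	0	0	0	0	0.208	0	0	0	0	0	0	0	0	0	0	0
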