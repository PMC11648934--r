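protein	loop_first	loop_second
CspA	D	E
CspB	F	E
CspC	A	E
CspD	K	A
CspE	A	E
CspF	T	T
CspG	N	E
CspH	I	P
CspI	T	E
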