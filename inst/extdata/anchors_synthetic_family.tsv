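name	ref_id	ref_pos	expected
loop1	KA01	42	K
loop2	KA01	43	A
k4	DE01	4	K
pos2	KE01	2	A
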