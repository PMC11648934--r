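name	left_id	left_end	right_id	right_skip	note
CspA13/D	CspA	13	CspD	10	CspA N-terminal 13 residues fused to the corresponding C-terminal part of CspD (CspD position = CspA position - 3); offsets transcribed from the parents' pairwise alignment, editable
CspA35/D	CspA	35	CspD	32	as above
CspA39/D	CspA	39	CspD	36	as above
CspA47/D	CspA	47	CspD	44	as above
CspA61/D	CspA	61	CspD	58	as above
CspD58/A	CspD	58	CspA	61	CspD N-terminal 58 residues fused to the corresponding C-terminal part of CspA (CspA position = CspD position + 3)
CspD46/A	CspD	46	CspA	49	as above
CspD36/A	CspD	36	CspA	39	as above
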