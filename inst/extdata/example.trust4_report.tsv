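#count	frequency	CDR3nt	CDR3aa	V	D	J	C
8	0.5000	TGTGCCAGCAGCTTAGGGTACTTT	CASSLGYF	TRBV7-2	.	TRBJ2-1	.
5	0.3125	TGTGCGAAAGATCGGGGGTATTTT	CAKDRGYF	IGHV3-23	IGHD3-10	IGHJ4	IGHM
2	0.1250	TGTCAACAGTATAATAGTTATTGG	CQQYNSYW	IGKV1-5	.	IGKJ1	IGKC
1	0.0625	TGTGCCAGCAGCTTAGGGTACTT	out_of_frame	TRBV7-2	.	TRBJ2-1	.
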