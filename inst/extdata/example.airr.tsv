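sequence_id	v_call	d_call	j_call	junction	junction_aa	productive	consensus_count	locus	complete_vdj
demo_seq0001	IGHV3-23*01	IGHD3-10*01	IGHJ4*01	TGTGCGAAAGATCGGGGGTATTTT	CAKDRGYF	TRUE	12	IGH	TRUE
demo_seq0002	IGHV3-23*01	IGHD3-10*01	IGHJ4*01	TGTGCGAAAGATCGGGGCTATTTT	CAKDRGYF	TRUE	3	IGH	TRUE
demo_seq0003	IGKV1-5*01		IGKJ1*01	TGTCAACAGTATAATAGTTATTGG	CQQYNSYW	TRUE	6	IGK	TRUE
demo_seq0004	TRBV7-2*01		TRBJ2-1*01	TGTGCCAGCAGCTTAGGGTACTTT	CASSLGYF	TRUE	4	TRB	TRUE
demo_seq0005	TRBV7-2*01		TRBJ2-1*01	TGTGCCAGCAGCTAAGGGTACTTT	CASS*GYF	FALSE	1	TRB	TRUE
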