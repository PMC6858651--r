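sample_id	os_months	os_event	age	grade	idh_status	standard_therapy
s1	13.5	1	60	G4	WT	1
s2	20.2	1	57	G3	WT	0
s3	94.5	0	38	G2	Mutant	1
s4			41	G2	Mutant	
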