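event_id	s1	s2	s3	s4
KIF4A|10001|AT|exon32	0.12	0.55	NA	0.90
GENE2|2|ES|exon7	0.40	0.41	0.39	0.44
GENE3|3|RI|exon3	0.00	1.00	0.25	0.75
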