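Hugo_Symbol	Tumor_Sample_Barcode	Variant_Classification	Variant_Type	t_alt_count	AF
TP53	P-0001	Missense_Mutation	SNP	120	0.0001
KRAS	P-0001	Nonsense_Mutation	SNP	88	
 zfhx3 	P-0002	Missense_Mutation	SNP	73	0.0002
STK11	P-0002	Frame_Shift_Del	DEL	61	
KEAP1	P-0003	In_Frame_Ins	INS	55	0.001
EGFR	P-0003	Silent	SNP	90	
BRAC2	P-0004	Splice_Site	SNP	47	
MET	P-0004	Intron	SNP	200	0.02
ALK	P-0005	3'UTR	SNP	66	
ROS1	P-0005	Translation_Start_Site	SNP	52	0.005
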