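sample_id	patient_id	timepoint	response	hr_status	her2_status
P1_pre	P1	pre	NR	Pos	Pos
P1_post	P1	post	NR	Pos	Pos
P2_pre	P2	pre	NR	Neg	Neg
P2_post	P2	post	NR	Neg	Neg
P3_pre	P3	pre	NR	Pos	Pos
P3_post	P3	post	NR	Pos	Pos
P4_pre	P4	pre	NR	Pos	Neg
P4_post	P4	post	NR	Pos	Neg
P5_pre	P5	pre	CR	Pos	Pos
P5_post	P5	post	CR	Pos	Pos
P6_pre	P6	pre	CR	Pos	Neg
P6_post	P6	post	CR	Pos	Neg
P7_pre	P7	pre	NR	Pos	Pos
P7_post	P7	post	NR	Pos	Pos
P8_pre	P8	pre	PR	Pos	Neg
P8_post	P8	post	PR	Pos	Neg
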