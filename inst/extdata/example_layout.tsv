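id	x	y	hemisphere	stream	level	analyzed
l_s1_l1	-4.5	0	left	1	1	TRUE
l_s1_l2	-3	1.5	left	1	2	TRUE
l_s1_l3	-4.5	3	left	1	3	TRUE
l_s1_l4	-3	4.5	left	1	4	TRUE
l_s2_l1	-7.5	0	left	2	1	TRUE
l_s2_l2	-6	1.5	left	2	2	TRUE
l_s2_l3	-7.5	3	left	2	3	TRUE
l_s2_l4	-6	4.5	left	2	4	TRUE
l_s3_l1	-10.5	0	left	3	1	TRUE
l_s3_l2	-9	1.5	left	3	2	TRUE
l_s3_l3	-10.5	3	left	3	3	TRUE
l_s3_l4	-9	4.5	left	3	4	TRUE
l_s4_l1	-13.5	0	left	4	1	TRUE
l_s4_l2	-12	1.5	left	4	2	TRUE
l_s4_l3	-13.5	3	left	4	3	TRUE
l_s4_l4	-12	4.5	left	4	4	TRUE
r_s1_l1	4.5	0	right	1	1	TRUE
r_s1_l2	3	1.5	right	1	2	TRUE
r_s1_l3	4.5	3	right	1	3	TRUE
r_s1_l4	3	4.5	right	1	4	TRUE
r_s2_l1	7.5	0	right	2	1	TRUE
r_s2_l2	6	1.5	right	2	2	TRUE
r_s2_l3	7.5	3	right	2	3	TRUE
r_s2_l4	6	4.5	right	2	4	TRUE
r_s3_l1	10.5	0	right	3	1	TRUE
r_s3_l2	9	1.5	right	3	2	TRUE
r_s3_l3	10.5	3	right	3	3	TRUE
r_s3_l4	9	4.5	right	3	4	TRUE
r_s4_l1	13.5	0	right	4	1	TRUE
r_s4_l2	12	1.5	right	4	2	TRUE
r_s4_l3	13.5	3	right	4	3	TRUE
r_s4_l4	12	4.5	right	4	4	TRUE
m_1	0.75	0	left	NA	NA	FALSE
m_2	-0.75	1	right	NA	NA	FALSE
m_3	0.75	2	left	NA	NA	FALSE
m_4	-0.75	3	right	NA	NA	FALSE
m_5	0.75	4	left	NA	NA	FALSE
m_6	-0.75	5	right	NA	NA	FALSE
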