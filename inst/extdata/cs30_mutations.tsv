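protein_id	mutation	label
CYP7B1	T297A	deleterious
CYP7B1	A394D	deleterious
CYP7B1	R417C	deleterious
CYP7B1	F470I	deleterious
CYP7B1	R486C	deleterious
CYP21A2	V139E	deleterious
CYP21A2	T295N	deleterious
CYP21A2	W302R	deleterious
CYP21A2	L353R	deleterious
CYP21A2	G375S	deleterious
CYP21A2	F404S	deleterious
CYP21A2	L446P	deleterious
CYP21A2	T450P	deleterious
CYP21A2	A265V	benign
CYP11B1	M88I	deleterious
CYP11B1	W116G	deleterious
CYP11B1	P159L	deleterious
CYP11B1	A165D	deleterious
CYP11B1	R366C	deleterious
CYP11B1	R384Q	deleterious
CYP11B1	T401A	deleterious
CYP27B1	G57V	deleterious
CYP27B1	G73W	deleterious
CYP27B1	L333F	deleterious
CYP27B1	R432C	deleterious
CYP27B1	R459C	deleterious
CYP27B1	R492W	deleterious
CYP27B1	G102E	deleterious
CYP27B1	P143L	deleterious
CYP27B1	D164N	deleterious
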