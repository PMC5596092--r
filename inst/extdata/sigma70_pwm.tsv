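box	pos	A	C	G	T
m35	1	0.05	0.05	0.05	0.85
m35	2	0.05	0.05	0.05	0.85
m35	3	0.05	0.05	0.85	0.05
m35	4	0.85	0.05	0.05	0.05
m35	5	0.05	0.85	0.05	0.05
m35	6	0.85	0.05	0.05	0.05
m10	1	0.05	0.05	0.05	0.85
m10	2	0.85	0.05	0.05	0.05
m10	3	0.05	0.05	0.05	0.85
m10	4	0.85	0.05	0.05	0.05
m10	5	0.85	0.05	0.05	0.05
m10	6	0.05	0.05	0.05	0.85
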