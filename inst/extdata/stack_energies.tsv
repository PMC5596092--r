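pair	CG	GC	GU	UG	AU	UA
CG	-3.3	-2.4	-1.75	-1.75	-2.1	-2.1
GC	-3.4	-3.3	-2.3	-2.0	-2.15	-2.4
GU	-2.0	-1.75	-0.85	-0.6	-1.25	-1.15
UG	-2.3	-1.75	-0.5	-0.85	-1.2	-1.15
AU	-2.4	-2.1	-1.15	-1.15	-0.9	-1.3
UA	-2.15	-2.1	-1.2	-1.25	-1.3	-0.9
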