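term_id	class
GO:0000001	membrane
GO:0000002	cell part
GO:0000003	intracellular part
GO:0000004	organelle
GO:0000005	catalytic activity
GO:0000006	binding
GO:0000007	transport
GO:0000008	structural molecule
GO:0000009	metabolic process
GO:0000010	biological regulation
GO:0000011	cellular process
GO:0000012	response to stimulus
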