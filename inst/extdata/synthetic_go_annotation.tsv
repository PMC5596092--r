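gene_id	term_id	namespace	term_name
SYN_00010	GO:0000009	biological_process	metabolic process
SYN_00020	GO:0000009	biological_process	metabolic process
SYN_00020	GO:0000001	cellular_component	membrane
SYN_00030	GO:0000003	cellular_component	intracellular part
SYN_00030	GO:0000004	cellular_component	organelle
SYN_00030	GO:0000008	molecular_function	structural molecule
SYN_00040	GO:0000011	biological_process	cellular process
SYN_00050	GO:0000012	biological_process	response to stimulus
SYN_00050	GO:0000003	cellular_component	intracellular part
SYN_00050	GO:0000001	cellular_component	membrane
SYN_00050	GO:0000007	molecular_function	transport
SYN_00060	GO:0000001	cellular_component	membrane
SYN_00060	GO:0000008	molecular_function	structural molecule
SYN_00070	GO:0000004	cellular_component	organelle
SYN_00070	GO:0000005	molecular_function	catalytic activity
SYN_00070	GO:0000002	cellular_component	cell part
SYN_00080	GO:0000008	molecular_function	structural molecule
SYN_00090	GO:0000006	molecular_function	binding
SYN_00090	GO:0000012	biological_process	response to stimulus
SYN_00090	GO:0000003	cellular_component	intracellular part
SYN_00100	GO:0000011	biological_process	cellular process
SYN_00110	GO:0000002	cellular_component	cell part
SYN_00120	GO:0000005	molecular_function	catalytic activity
SYN_00120	GO:0000008	molecular_function	structural molecule
SYN_00130	GO:0000006	molecular_function	binding
SYN_00140	GO:0000012	biological_process	response to stimulus
SYN_00140	GO:0000003	cellular_component	intracellular part
SYN_00150	GO:0000012	biological_process	response to stimulus
SYN_00150	GO:0000005	molecular_function	catalytic activity
SYN_00150	GO:0000004	cellular_component	organelle
SYN_00160	GO:0000008	molecular_function	structural molecule
SYN_00160	GO:0000001	cellular_component	membrane
SYN_00160	GO:0000007	molecular_function	transport
SYN_00160	GO:0000009	biological_process	metabolic process
SYN_00170	GO:0000004	cellular_component	organelle
SYN_00180	GO:0000007	molecular_function	transport
SYN_00180	GO:0000011	biological_process	cellular process
SYN_00190	GO:0000003	cellular_component	intracellular part
SYN_00190	GO:0000002	cellular_component	cell part
SYN_00190	GO:0000005	molecular_function	catalytic activity
SYN_00200	GO:0000002	cellular_component	cell part
SYN_00210	GO:0000002	cellular_component	cell part
SYN_00210	GO:0000005	molecular_function	catalytic activity
SYN_00220	GO:0000010	biological_process	biological regulation
SYN_00220	GO:0000005	molecular_function	catalytic activity
SYN_00220	GO:0000007	molecular_function	transport
SYN_00230	GO:0000008	molecular_function	structural molecule
SYN_00230	GO:0000003	cellular_component	intracellular part
SYN_00240	GO:0000004	cellular_component	organelle
SYN_00250	GO:0000004	cellular_component	organelle
SYN_00260	GO:0000011	biological_process	cellular process
SYN_00260	GO:0000006	molecular_function	binding
SYN_00260	GO:0000010	biological_process	biological regulation
SYN_00260	GO:0000005	molecular_function	catalytic activity
SYN_00270	GO:0000007	molecular_function	transport
SYN_00270	GO:0000005	molecular_function	catalytic activity
SYN_00280	GO:0000012	biological_process	response to stimulus
SYN_00280	GO:0000001	cellular_component	membrane
SYN_00280	GO:0000005	molecular_function	catalytic activity
SYN_00290	GO:0000008	molecular_function	structural molecule
SYN_00290	GO:0000004	cellular_component	organelle
SYN_00290	GO:0000012	biological_process	response to stimulus
SYN_00300	GO:0000001	cellular_component	membrane
SYN_00300	GO:0000007	molecular_function	transport
SYN_00300	GO:0000006	molecular_function	binding
SYN_00310	GO:0000012	biological_process	response to stimulus
SYN_00320	GO:0000003	cellular_component	intracellular part
SYN_00320	GO:0000006	molecular_function	binding
SYN_00320	GO:0000007	molecular_function	transport
SYN_00330	GO:0000003	cellular_component	intracellular part
SYN_00330	GO:0000010	biological_process	biological regulation
SYN_00330	GO:0000004	cellular_component	organelle
SYN_00340	GO:0000004	cellular_component	organelle
SYN_00350	GO:0000002	cellular_component	cell part
SYN_00360	GO:0000011	biological_process	cellular process
SYN_00370	GO:0000009	biological_process	metabolic process
SYN_00380	GO:0000008	molecular_function	structural molecule
SYN_00380	GO:0000001	cellular_component	membrane
SYN_00390	GO:0000002	cellular_component	cell part
SYN_00390	GO:0000003	cellular_component	intracellular part
SYN_00390	GO:0000011	biological_process	cellular process
SYN_00390	GO:0000004	cellular_component	organelle
SYN_00400	GO:0000012	biological_process	response to stimulus
SYN_00400	GO:0000009	biological_process	metabolic process
SYN_00400	GO:0000001	cellular_component	membrane
SYN_00410	GO:0000007	molecular_function	transport
SYN_00410	GO:0000011	biological_process	cellular process
SYN_00420	GO:0000008	molecular_function	structural molecule
SYN_00420	GO:0000006	molecular_function	binding
SYN_00420	GO:0000012	biological_process	response to stimulus
SYN_00430	GO:0000005	molecular_function	catalytic activity
SYN_00430	GO:0000011	biological_process	cellular process
SYN_00430	GO:0000002	cellular_component	cell part
SYN_00430	GO:0000006	molecular_function	binding
SYN_00440	GO:0000012	biological_process	response to stimulus
SYN_00440	GO:0000008	molecular_function	structural molecule
SYN_00450	GO:0000011	biological_process	cellular process
SYN_00450	GO:0000005	molecular_function	catalytic activity
SYN_00450	GO:0000004	cellular_component	organelle
SYN_00450	GO:0000008	molecular_function	structural molecule
SYN_00460	GO:0000003	cellular_component	intracellular part
SYN_00460	GO:0000012	biological_process	response to stimulus
SYN_00470	GO:0000003	cellular_component	intracellular part
SYN_00470	GO:0000010	biological_process	biological regulation
SYN_00470	GO:0000004	cellular_component	organelle
SYN_00470	GO:0000001	cellular_component	membrane
SYN_00480	GO:0000007	molecular_function	transport
SYN_00490	GO:0000004	cellular_component	organelle
SYN_00490	GO:0000005	molecular_function	catalytic activity
SYN_00500	GO:0000006	molecular_function	binding
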