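# Domain-registry template for the experimentally determined M-band Ig
# domains. Point the file column at local copies of the coordinate files
# (they accompany the study as supplementary data / PDB depositions);
# chain A is the analysis chain wherever multiple copies are present.
# tag_local flags cleaved-expression-tag residues to exclude from
# fingerprint computations.
domain	file	chain	offset	uniprot_id	pdb_id	model	tag_local
M1	2bk8.pdb	A	32489	Q8WZ42	2bk8	1	
M3	6hci.pdb	A	32715	Q8WZ42	6hci	1	
M4	6h4l.pdb	A	33294	Q8WZ42	6h4l	1	
M5	1ncu.pdb	A	33482	Q8WZ42	1ncu	1	
M7	3puc.pdb	A	NA	Q8WZ42	3puc	1	
M10	3q5o.pdb	A	34249	Q8WZ42	3q5o	1	
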