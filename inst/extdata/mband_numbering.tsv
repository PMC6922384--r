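# Full-titin (UniProt Q8WZ42) numbering offsets for the M-band Ig domains
# with structures: global position = domain-local index + offset. Lengths
# are the nominal 100-residue domain spans (inter-domain linkers are long
# enough that the spans do not overlap). M7's offset is not derivable from
# the printed variant pairs and is left out.
domain	offset	length	uniprot_id
M1	32489	100	Q8WZ42
M3	32715	100	Q8WZ42
M4	33294	100	Q8WZ42
M5	33482	100	Q8WZ42
M10	34249	100	Q8WZ42
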