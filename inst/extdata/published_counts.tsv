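name	value
peptides_initial	4791
ensembl_mapped	404
pepquery_validated	1558
coding_peptides	580
pseudogene_peptides	59
lncrna_peptides	87
tec_peptides	1
norf_peptides	831
comparison_total	672
comparison_known	250
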