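family	category
5S_rRNA	rRNA
5_8S_rRNA	rRNA
SSU_rRNA_eukarya	rRNA
LSU_rRNA_eukarya	rRNA
tRNA	tRNA
tRNA-Sec	tRNA
U1	snRNA
U2	snRNA
U4	snRNA
U5	snRNA
U6	snRNA
U6atac	snRNA
U11	snRNA
U12	snRNA
snoZ196	snoRNA
SNORD14	snoRNA
SNORA64	snoRNA
snoR9	snoRNA
U3	snoRNA
RNase_MRP	other_structural
RNaseP_nuc	other_structural
SRP_euk_arch	other_structural
Telomerase-vert	other_structural
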