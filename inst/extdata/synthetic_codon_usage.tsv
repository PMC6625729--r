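codon	frequency
TTT	36.6
TTC	37.5
TTA	11.8
TTG	33.3
TCT	25.8
TCC	21
TCA	29.6
TCG	5.8
TAT	26.5
TAC	28.4
TGT	18.6
TGC	28.9
TGG	37.4
CTT	10.6
CTC	18.8
CTA	37.6
CTG	39.1
CCT	5.1
CCC	19.3
CCA	22.6
CCG	36.2
CAT	6
CAC	39.6
CAA	37.9
CAG	3.8
CGT	20.8
CGC	15.9
CGA	36.3
CGG	18.2
ATT	33.5
ATC	29.6
ATA	32.5
ATG	15.8
ACT	27.6
ACC	0.7
ACA	33.4
ACG	0.8
AAT	8.7
AAC	36.3
AAA	24.7
AAG	15.5
AGT	17.7
AGC	2
AGA	39
AGG	17.6
GTT	38.3
GTC	35.6
GTA	25.8
GTG	38.9
GCT	24.9
GCC	13.7
GCA	14.2
GCG	16.2
GAT	31.5
GAC	2
GAA	30.1
GAG	27.3
GGT	7.3
GGC	10.8
GGA	20.8
GGG	27.2
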