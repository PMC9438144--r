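gene	mrna_log2fc	node_strength
RAB3B	-1.370	3
LRRTM2	-1.051	2
NOX5	-1.051	1
FAT3	-1.003	1
CBARP	-0.955	1
BEND6	-0.890	1
RPS27A	-0.675	1
TBCA	-0.639	1
FRG1B	-0.620	1
ZNF730	1.175	-1
ZNF704	0.967	-1
MKI67	0.826	-1
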