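gene	mrna_log2fc	node_strength
PLCXD2	-1.337	1
TNF	2.814	-1
EGR1	2.616	-1
EREG	3.063	-1
CD83	2.504	-1
NFKBIA	1.861	-1
IER3	1.810	-1
TNFAIP6	2.464	-1
ID1	1.723	-1
OSR2	1.936	-1
NR4A2	1.752	-1
CNTNAP3	2.178	-1
FOSB	1.524	-1
IL6	1.826	-1
EGR3	1.694	-1
DUSP1	1.265	-1
SOCS3	1.284	-1
SAT1	1.147	-1
RGS1	1.681	-1
PLAU	1.312	-1
MIPOL1	1.252	-1
JUNB	1.059	-1
SGK1	0.975	-1
MAP3K7CL	0.878	-1
CXCL8	2.806	-2
PLAUR	1.428	-2
DUSP2	1.521	-2
RBKS	1.202	-2
GXYLT2	1.888	-3
SOD2	1.429	-4
SOCS1	1.033	-4
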