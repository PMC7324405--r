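enzyme	pathway_group	product_basin	flux
NiFe	NF-A	NFA-1	4.06e-5
NiFe	NF-A	NFA-2	3.09e-5
NiFe	NF-A	NFA-3	2.64e-5
NiFe	NF-B	NFB-1	2.11e-6
NiFe	NF-B	NFB-2	1.10e-5
NiFe	NF-C	NFC-1	1.82e-6
NiFeSe	NFS-A	NFSA-1	2.71e-6
NiFeSe	NFS-A	NFSA-2	1.80e-6
NiFeSe	NFS-A	NFSA-3	1.88e-6
NiFeSe	NFS-B	NFSB-1	6.95e-6
NiFeSe	NFS-C	NFSC-1	1.72e-6
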