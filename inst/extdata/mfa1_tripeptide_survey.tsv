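gene	taxon	species	accession	tripeptide	count
MFalpha1	F	NA	NA	APV	24
MFalpha1	F	NA	NA	API	8
MFalpha1	F	NA	NA	IPV	1
MFalpha1	F	NA	NA	VPA	1
MFalpha1	F	NA	NA	APA	1
MFalpha1	F	NA	NA	APT	4
MFalpha1	F	NA	NA	AIA	4
MFalpha1	F	NA	NA	TAI	1
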