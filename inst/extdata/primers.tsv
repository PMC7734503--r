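name	direction	sequence	marker	aliases
ITS1F	fwd	CTTGGTCATTTAGAGGAAGTAA	ITS1	ITS1-F
ITS1	fwd	TCCGTAGGTGAACCTGCGG	ITS1
ITS5	fwd	GGAAGTAAAAGTCGTAACAAGG	ITS1
ITS2	rev	GCTGCGTTCTTCATCGATGC	ITS1	ITS2R
ITS3	fwd	GCATCGATGAAGAACGCAGC	ITS2
fITS7	fwd	GTGARTCATCGAATCTTTG	ITS2	fITS-7
gITS7	fwd	GTGARTCATCGARTCTTTG	ITS2
ITS86F	fwd	GTGAATCATCGAATCTTTGAA	ITS2	ITS86
5.8S-Fun	fwd	AACTTTYRRCAAYGGATCWCT	ITS2	58S-Fun
ITS4	rev	TCCTCCGCTTATTGATATGC	ITS2	ITS-4
ITS4-Fun	rev	AGCCTCCGCTTATTGATATGCTTAART	ITS2	ITS4Fun
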