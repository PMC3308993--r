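# Transcriptome presence/absence evidence for the missing plastid genes:
# petA, petN, ycf3, clpP and ftsH have transcripts in both the euglena
# and the eutreptiella transcriptome; ccsA only in the euglena one.
gene	source	present
petA	euglena	1
petA	eutreptiella	1
petN	euglena	1
petN	eutreptiella	1
ycf3	euglena	1
ycf3	eutreptiella	1
clpP	euglena	1
clpP	eutreptiella	1
ftsH	euglena	1
ftsH	eutreptiella	1
ccsA	euglena	1
ccsA	eutreptiella	0
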