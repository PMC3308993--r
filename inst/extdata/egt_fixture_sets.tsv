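# Protein-coding gene content fixture for the euglenid endosymbiotic
# gene-transfer worked example.  Membership flags: pyramimonas is the
# algal reference (closest extant relative of the euglenid plastid),
# euglena and eutreptiella are the two descendant euglenid plastids.
# The shared core below is a representative standard plastid gene set
# (synthetic stand-in for the unpublished full annotation lists); the
# reference-only block is the worked-example missing-gene list (the three
# ycfx placeholders stand for unnamed conserved ORFs of unknown
# function completing the 24-gene set), and the lineage-specific blocks
# follow the worked-example enumerations.
gene	pyramimonas	euglena	eutreptiella
psbA	1	1	1
psbB	1	1	1
psbC	1	1	1
psbD	1	1	1
psbE	1	1	1
psbF	1	1	1
psbH	1	1	1
psbI	1	1	1
psbJ	1	1	1
psbK	1	1	1
psbL	1	1	1
psbM	1	1	1
psbN	1	1	1
psbT	1	1	1
psbZ	1	1	1
psaA	1	1	1
psaB	1	1	1
psaC	1	1	1
psaJ	1	1	1
petB	1	1	1
petD	1	1	1
petG	1	1	1
petL	1	1	1
atpA	1	1	1
atpB	1	1	1
atpE	1	1	1
atpF	1	1	1
atpH	1	1	1
atpI	1	1	1
rbcL	1	1	1
ycf4	1	1	1
rpoA	1	1	1
rpoB	1	1	1
rpoC1	1	1	1
rpoC2	1	1	1
tufA	1	1	1
rps2	1	1	1
rps3	1	1	1
rps4	1	1	1
rps7	1	1	1
rps8	1	1	1
rps9	1	1	1
rps11	1	1	1
rps12	1	1	1
rps14	1	1	1
rps18	1	1	1
rps19	1	1	1
rpl2	1	1	1
rpl5	1	1	1
rpl12	1	1	1
rpl14	1	1	1
rpl16	1	1	1
rpl20	1	1	1
rpl22	1	1	1
rpl23	1	1	1
rpl32	1	1	1
rpl36	1	1	1
mat1	0	1	1
ndhA	1	0	0
ndhB	1	0	0
ndhC	1	0	0
ndhD	1	0	0
ndhE	1	0	0
ndhF	1	0	0
ndhG	1	0	0
ndhH	1	0	0
ndhI	1	0	0
ndhJ	1	0	0
petA	1	0	0
petN	1	0	0
chlL	1	0	0
chlN	1	0	0
chlB	1	0	0
ccsA	1	0	0
psaI	1	0	0
infA	1	0	0
clpP	1	0	0
ftsH	1	0	0
ycf3	1	0	0
ycfx1	1	0	0
ycfx2	1	0	0
ycfx3	1	0	0
ycf65	1	0	1
mat2	0	1	0
roaA	0	1	0
orf506	0	1	0
orf516	0	1	0
orf528	0	1	0
orf546	0	1	0
orf558	0	1	0
orf570	0	1	0
orf291	0	0	1
orf386	0	0	1
orf248	0	0	1
orf372	0	0	1
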