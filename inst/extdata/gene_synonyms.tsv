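alias	canonical
ycf13	mat1
rpl3	ycf65
ycf9	psbZ
rrn16s	rrn16
rrn23s	rrn23
16s_rrna	rrn16
23s_rrna	rrn23
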