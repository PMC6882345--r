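# gwasgrid configuration: cell classification rules + options
idx	min.count	maf	conseq	col	report
1	1	FALSE	FALSE	black	FALSE
2	1	FALSE	TRUE	light pink	TRUE
3	1	TRUE	FALSE	green	FALSE
4	1	TRUE	TRUE	dark magenta	TRUE
5	2	FALSE	FALSE	blue	FALSE
6	2	FALSE	TRUE	pink	TRUE
7	2	TRUE	FALSE	red	FALSE
8	2	TRUE	TRUE	cyan	TRUE

[options]
chunk.bp=3000000
pbin=0.125
cap.nlp=20
maf.threshold=0.05
fdr.q=0.05
annotation.mode=table
table.capacity=130
output.format=pdf
tiff.dpi=300
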