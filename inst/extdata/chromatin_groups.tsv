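group	h3k4me3	h3k27ac	tss_distance	accessibility	timing	n_cres
A	+	+	0-5 kb	independent	open in other cell types, always accessible	249
A	+	+	0-5 kb	dependent	retina-specific, late accessibility	632
C	-	+	5-500 kb	independent	retina-specific, early accessibility	311
C	-	+	5-500 kb	dependent	retina-specific, late accessibility	366
D	-	-	5-500 kb	independent	retina-specific, intermediate accessibility	76
D	-	-	5-500 kb	dependent	retina-specific, early accessibility	89
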