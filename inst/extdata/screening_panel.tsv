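laboratory	sample	flower_color	actin	P-35S	T-nos	P-nos/nptII	PxhG1	PxhG2
WFSR	African Sunset	Orange	24.6	23.6	n.d.	+	23.0	-
LAU	Pegasus Orange Morn	Orange	29.2	+	n.d.	25.9	28.5	-
LAU	Table Orange	Orange	27.3	+	n.d.	26.3	28.7	-
LAU	Landgard	Orange red	27.2	+	n.d.	n.d.	27.9	-
LAU	Potunia Plus Papaya	Orange	26.8	+	n.d.	25.2	27.8	-
LAU	Peppy Red	Red white striped	26.9	+	n.d.	25.4	27.9	-
LAU	Crazytunia Citrus Twist	Yellow red stripes	25.9	+	n.d.	24.3	27.1	-
LAU	Blast Rose	Orange	26.9	+	n.d.	n.d.	27.4	-
LAU	RL01-17	Orange	30.1	+	n.d.	n.d.	-	-
LAU	RL01-24	Orange	25.2	+	n.d.	n.d.	-	-
LAU	Raspberry Blast	Pink (with fading)	26.9	+	+	26.0	-	27.1
LAU	Mini Blast Rose	Pink white striped	25.6	+	+	26.2	-	27.0
LGL	Bonnie Orange	Orange-apricot	22.4	24.9	-	24.4	24.3	-
LGL	Cascadias Red Lips	Red	22.5	24.0	-	23.2	23.2	-
LGL	Potunia Plus Red 2016	Red	23.1	25.4	-	24.5	24.8	-
LGL	Classic Red	Red	22.9	-	-	-	-	-
LGL	Orange yellow center 749 (07336)	Orange	23.2	25.4	-	24.9	25.0	-
LGL	Sentunia (2.0) Gshell Orange	Orange	22.8	24.9	-	24.4	24.6	-
LGL	Charms Flame	Yellow-red	23.3	25.8	-	24.4	25.2	-
LGL	Sentunia 2.0 Rose Coral	Orange apricot	22.2	24.9	-	24.4	24.3	-
LGL	Bingo Coral Blast	Pink/red with white	22.9	25.4	-	24.6	24.8	-
LGL	Crazytunia Citrus Twist	Red	22.8	25.5	-	24.8	24.7	-
LGL	Raspberry Blast (DNA from LAU)	Pink	n.d.	n.d.	n.d.	n.d.	n.d.	28.9
CVUAMEL	Pegasus Orange Morn	Orange	25.7	27.7	n.d.	26.7	26.1	-
CVUAMEL	Table Orange	Orange	25.2	27.5	n.d.	25.8	26.2	-
CVUAMEL	Pegasus Purple	Purple	26.6	-	n.d.	-	-	-
CVUAMEL	Special Mango	Yellow	26.3	-	n.d.	-	-	-
CVUAMEL	Pegasus Table Red Star	White-red stripes	25.6	26.7	n.d.	26.2	25.1	-
LUFA	Mini Blast Rose	Pink	22.8	+	+	+	-	26.4
LUFA	Supertunia Flamingo	Pink	22.3	+	+	+	-	25.5
LUFA	Raspberry Blast	Pink	22.4	+	+	+	-	25.8
LUFA	Johnny Flame	Red/salmon	22.7	-	-	-	-	-
LUFA	Pegasus Orange	Orange	22.5	+	-	+	23.5	-
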