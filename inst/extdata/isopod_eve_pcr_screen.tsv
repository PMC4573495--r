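viral_family	eve	An1	An2	An3	At	Ad	Av
Bunyaviridae	7	+	-	+	-	-	-
Bunyaviridae	12	+	+	+	+	+	-
Mononegavirales	15	+	-	-	-	-	-
Mononegavirales	16	+	-	-	-	-	-
Totiviridae	21	+	+	+	-	-	+
Totiviridae	23	+	+	+	-	-	-
Circoviridae	44	+	+	+	+	-	-
Circoviridae	45	+	+	+	-	-	-
Circoviridae	46	+	+	+	-	-	+
Circoviridae	50	+	+	+	+	-
Parvoviridae	67	+	+	-	+	+	-
Parvoviridae	69	+	+	+	-	-	-
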