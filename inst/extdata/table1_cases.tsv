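sample_id	group	age	distance_from_tumour	er	pr	her2	stage	cancer_history	prior_study
319H	HN	34	<2 cm	-	-	-	IIIA	NA	FALSE
316H	HN	39	<2 cm	+	-	-	IIA	NA	TRUE
379H	HN	43	<2 cm	+	+	+	I	NA	FALSE
251H	HN	45	<2 cm	+	+	-	0	NA	TRUE
289H	HN	47	<2 cm	-	-	-	IIA	NA	FALSE
364H	HN	47	>2 cm	-	-	+	IIIA	NA	FALSE
342H	HN	48	<2 cm	-	-	-	IIA	NA	FALSE
304BH	HN	49	<2 cm	+	+	+	I	NA	TRUE
273H	HN	49	<2 cm	-	-	+	III	NA	FALSE
380H	HN	53	<2 cm	+	+	+	IIA	NA	FALSE
446BH	HN	54	>2 cm	+	+	-	IIIA	NA	FALSE
237H	HN	55	?	+	-	-	I	NA	TRUE
322H	HN	58	<2 cm	-	-	-	I	NA	FALSE
272H	HN	58	>2 cm	-	-	+	IIIC	NA	FALSE
388AH	HN	58	<2 cm	+	-	-	I	NA	FALSE
232H	HN	59	>2 cm	+	+	na	0	NA	FALSE
226H	HN	61	<2 cm	-	-	na	IIIA	NA	TRUE
333H	HN	76	>2 cm	-	-	+	IIB	NA	FALSE
360R	RM	36	NA	NA	NA	NA	NA	NA	TRUE
352R	RM	41	NA	NA	NA	NA	NA	NA	TRUE
347R	RM	43	NA	NA	NA	NA	NA	NA	TRUE
278R	RM	44	NA	NA	NA	NA	NA	NA	TRUE
373R	RM	44	NA	NA	NA	NA	NA	NA	FALSE
350R	RM	47	NA	NA	NA	NA	NA	NA	TRUE
309R	RM	49	NA	NA	NA	NA	NA	NA	TRUE
357R	RM	49	NA	NA	NA	NA	NA	NA	TRUE
368R	RM	49	NA	NA	NA	NA	NA	NA	TRUE
288R	RM	52	NA	NA	NA	NA	NA	NA	TRUE
402R	RM	55	NA	NA	NA	NA	NA	NA	FALSE
383R	RM	55	NA	NA	NA	NA	NA	NA	FALSE
406R	RM	56	NA	NA	NA	NA	NA	NA	FALSE
396R	RM	57	NA	NA	NA	NA	NA	NA	FALSE
361R	RM	57	NA	NA	NA	NA	NA	NA	TRUE
419R	RM	57	NA	NA	NA	NA	NA	NA	FALSE
310R	RM	60	NA	NA	NA	NA	NA	NA	TRUE
305R	RM	75	NA	NA	NA	NA	NA	NA	FALSE
395P	PM	35	NA	NA	NA	NA	NA	+	FALSE
276P	PM	36	NA	NA	NA	NA	NA	-	FALSE
451P	PM	43	NA	NA	NA	NA	NA	+	FALSE
242P	PM	46	NA	NA	NA	NA	NA	+	FALSE
446AP	PM	54	NA	NA	NA	NA	NA	+	FALSE
249P	PM	57	NA	NA	NA	NA	NA	-	FALSE
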