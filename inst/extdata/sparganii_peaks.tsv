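peak_id	rt_min	observed_mz	known_formula	printed_error_ppm	compound
SL1	0.55	104.1072	C5H13NO	2.0	Choline
SL2	0.57	175.1184	C6H14N4O2	-3.2	Arginine
SL3	0.62	138.0545	C7H7NO2	-3.4	Trigonelline
SL4	0.86	136.0617	C5H5N5	-2.7	Adenine
SL5	0.86	124.0394	C6H5NO2	-2.5	Nicotinic acid
SL6	1.27	113.0346	C4H4N2O2	-3.1	Uracil
SL7	1.35	117.0195	C4H6O4	1.4	Succinic acid
SL8	1.65	182.0812	C9H11NO3	0.2	Tyrosine
SL9	1.62	132.1015	C6H13NO2	-3.1	D-Tert-Leucine
SL10	2.13	268.1038	C10H13N5O4	-1.2	Adenine nucleoside
SL11	4.14	167.0352	C8H8O4	1.3	Vanillic acid
SL12	4.19	166.0853	C9H11NO2	-1.5	Phenylalanine
SL13	6.07	137.0249	C7H6O3	3.5	4-Hydroxybenzoic acid
SL14	7.37	227.1028	C10H14N2O5	0.7	Carbidopa
SL15	9.76	179.0349	C9H8O4	5.7	Caffeic acid
SL16	10.02	123.0439	C7H6O2	-1.3	Benzoic acid
SL17	10.44	253.0716	C12H14O6	-0.6	Hwanggeumchal B
SL18	12.88	445.1336	C19H26O12	-3.5	Hydroxymethoxyphenyl glucopyranoside derivative
SL19	13.57	253.0716	C12H14O6	-0.6	1-Caffeoylglycerol
SL20	13.69	237.0764	C12H14O5	-1.9	Coumaroyl dihydroxypropyl ester (E)
SL21	15.55	163.0404	C9H8O3	2.0	4-Coumaric acid
SL22	17.72	237.0768	C12H14O5	-0.2	1-O-p-coumaroylglycerol
SL23	17.74	193.0505	C10H10O4	5.0	Ferulic acid
SL24	20.88	267.0873	C13H16O6	-0.4	Feruloyl dihydroxypropyl ester (2Z)
SL25	21.11	267.0875	C13H16O6	0.3	1-O-Trans-Feruloylglycerol
SL26	24.37	219.0661	C12H12O4	4.2	Decarboxy-citrinone
SL27	29.2	609.1450	C27H30O16	-1.8	Rutin
SL28	29.26	447.1279	C22H22O10	-1.5	Tilianin
SL29	29.55	261.1337	C12H22O6	-2.5	9-(Dihydroxypropyloxy)-9-oxononanoic acid
SL30	30.18	187.0980	C9H16O4	2.2	Azelaic acid
SL31	32.53	623.1621	C28H32O16	0.5	Narcissin
SL32	35.33	381.1180	C18H20O9	0.0	Methyloxobenzopyranyl glucuronide ethyl ester
SL33	35.66	283.0612	C16H12O5	0.0	Acacetin
SL34	35.75	429.1168	C22H22O9	-2.8	Feruloyl-caffeoylglycerol
SL35	37.29	413.1224	C22H22O8	-4.3	p-Coumaroyl-feruloylglycerol
SL36	37.42	381.1131	C21H20O7	1.5	1,3-O-Di-trans-p-coumaroylglycerol
SL37	37.43	443.1324	C23H24O9	-5.3	1,3-O-Diferuloyl glycerol
SL38	37.45	413.1226	C22H22O8	-1.2	1-O-Feruloyl-3-O-p-coumaroylglycerol
SL39	38.88	283.0605	C16H12O5	-2.5	Methyl dihydroxy(hydroxyphenylethynyl)benzoate
SL40	40.359	327.21714	C18H31O5	1.6	Trihydroxyoctadecadienoic acid
SL41	41.74	329.2320	C18H34O5	-4.1	Sanleng acid
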