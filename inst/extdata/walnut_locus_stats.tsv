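locus	n	A	He	Ho	F
WGA001	702	13	0.810	0.605	0.253
WGA004	666	12	0.716	0.536	0.252
WGA009	662	12	0.762	0.650	0.148
WGA069	668	14	0.830	0.603	0.273
WGA089	709	8	0.682	0.495	0.274
WGA106	702	7	0.422	0.339	0.196
WGA118	701	16	0.743	0.615	0.173
WGA178	653	13	0.753	0.651	0.136
WGA202	675	20	0.841	0.631	0.250
WGA223	674	15	0.798	0.527	0.341
WGA225	657	10	0.475	0.327	0.311
WGA237	687	8	0.601	0.412	0.315
WGA318	651	19	0.864	0.399	0.538
WGA321	701	12	0.712	0.589	0.173
WGA331	687	9	0.631	0.408	0.354
WGA332	694	11	0.660	0.532	0.194
WGA338	693	9	0.509	0.427	0.161
WGA349	644	19	0.836	0.326	0.610
WGA384	676	8	0.659	0.448	0.320
Mean	679	12	0.700	0.501	0.285
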