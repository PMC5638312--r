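locus	HT	HG	DGT	GGT	within
WGA001	0.811	0.734	0.077	0.095	0.905
WGA004	0.688	0.617	0.071	0.103	0.897
WGA009	0.770	0.687	0.082	0.107	0.893
WGA069	0.829	0.767	0.062	0.075	0.925
WGA089	0.684	0.572	0.112	0.163	0.837
WGA106	0.418	0.381	0.038	0.090	0.910
WGA118	0.781	0.675	0.106	0.136	0.864
WGA178	0.749	0.694	0.055	0.073	0.927
WGA202	0.857	0.766	0.091	0.106	0.894
WGA223	0.809	0.719	0.090	0.111	0.889
WGA225	0.532	0.471	0.061	0.115	0.885
WGA237	0.587	0.511	0.076	0.130	0.870
WGA318	0.857	0.671	0.185	0.216	0.784
WGA321	0.746	0.671	0.074	0.100	0.900
WGA331	0.650	0.596	0.054	0.083	0.917
WGA332	0.659	0.581	0.078	0.119	0.881
WGA338	0.496	0.438	0.058	0.118	0.882
WGA349	0.873	0.726	0.147	0.169	0.831
WGA384	0.625	0.486	0.139	0.222	0.778
Mean	0.706	0.619	0.087	0.124	0.876
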