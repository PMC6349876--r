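x	y	z
0	0	0
0.1458	0	0
0.200948	0.142179	0
0.290837	0.174218	0.077446
0.199382	-0.077212	-0.120733
0.146345	0.226294	-0.087211
0.189942	0.365047	-0.097431
0.174975	0.43752	0.035911
0.266654	0.506422	0.080091
0.110977	0.43815	-0.206195
0.059084	0.421195	0.098882
0.031935	0.484984	0.227145
0.135199	0.444521	0.331814
0.188377	0.529393	0.40304
-0.10881	0.449812	0.275753
0.16261	0.314742	0.340091
0.259439	0.262851	0.435951
0.396427	0.326855	0.416103
0.459666	0.369948	0.512271
0.270255	0.11069	0.424153
0.441019	0.332435	0.291032
0.570435	0.391113	0.258382
0.578813	0.535899	0.305531
0.677455	0.575881	0.366976
0.596383	0.383235	0.107804
0.474815	0.613271	0.276198
0.470223	0.753598	0.315505
0.484461	0.769053	0.46655
0.562146	0.851772	0.513741
0.339952	0.8183	0.268048
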