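x	y	z
-0.477322	-0.010991	-0.002806
-0.355203	0.024586	0.068459
-0.232067	-0.032037	-0.001451
-0.213193	-0.153395	-0.005981
-0.361126	-0.025113	0.213041
-0.149226	0.056754	-0.05545
-0.027885	0.015826	-0.125157
0.096437	0.072289	-0.057245
0.118	0.193283	-0.057245
-0.032618	0.060182	-0.27151
0.177253	-0.016228	0.000165
0.299432	0.024586	0.068459
0.42251	-0.03713	0.002891
0.441379	-0.158487	0.007461
0.293629	-0.014127	0.216367
0.477322	0.490991	-0.002806
0.355203	0.455414	0.068459
0.232067	0.512037	-0.001451
0.213193	0.633395	-0.005981
0.361126	0.505113	0.213041
0.149226	0.423246	-0.05545
0.027885	0.464174	-0.125157
-0.096437	0.407711	-0.057245
-0.118	0.286717	-0.057245
0.032618	0.419818	-0.27151
-0.177253	0.496228	0.000165
-0.299432	0.455414	0.068459
-0.42251	0.51713	0.002891
-0.441379	0.638487	0.007461
-0.293629	0.494127	0.216367
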