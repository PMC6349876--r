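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
-0.357322	0.469009	-0.002806
-0.235203	0.504586	0.068459
-0.112067	0.447963	-0.001451
-0.093193	0.326605	-0.005981
-0.241126	0.454887	0.213041
-0.029226	0.536754	-0.05545
0.092115	0.495826	-0.125157
0.216437	0.552289	-0.057245
0.238	0.673283	-0.057245
0.087382	0.540182	-0.27151
0.297253	0.463772	0.000165
0.419432	0.504586	0.068459
0.54251	0.44287	0.002891
0.561379	0.321513	0.007461
0.413629	0.465873	0.216367
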