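ATF	1.0
2	6
"Type=GenePix Results 3"
"Wavelengths=635"
Block	Row	Column	Name	ID	F635 Median
1	1	1	pep1	V1	124
1	1	2	pep2	V2	369
1	1	3	pep3	V3	222
1	1	4	pep4	V4	193
1	1	5	pep5	V5	555
1	1	6	pep6	V6	239
1	1	7	empty	V7	258
1	1	8	pep7	V8	168
1	1	9	pep8	V9	236
1	1	10	pep9	V10	248
1	1	11	pep10	V11	403
1	1	12	pep11	V12	519
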