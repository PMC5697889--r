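# Relative weighted profiles (%) of lignocellulolytic glycoside hydrolase
# families across six microbial communities, as published. Percentages are
# relative to all lignocellulolytic GHs in each community, at 1 decimal.
family	activity	koala	wombat	wallaby_foregut	cow_rumen	termite_hindgut	compost
GH5	cellulose	6.9	7.5	3.7	1.0	13.9	3.2
GH6	endoglucanase	0.0	0.0	0.0	0.0	0.0	2.1
GH7	endoglucanase	0.0	0.0	0.0	0.0	0.0	0.1
GH9	endoglucanase	1.5	4.3	0.0	0.9	4.3	4.3
GH44	endoglucanase	0.5	0.2	0.0	0.0	0.8	0.4
GH45	endoglucanase	0.0	0.0	0.0	0.0	0.6	0.0
GH48	endo-processive cellulases	0.0	0.3	0.0	0.0	0.0	0.5
GH8	endo-xylanases	0.5	1.1	0.4	0.5	2.7	0.5
GH10	endo-1,4-b-xylanase	1.4	3.6	4.1	1.0	9.9	8.9
GH11	xylanase	0.0	2.9	0.0	0.1	1.9	1.4
GH12	endoglucanase & xyloglucan hydrolysis	0.0	0.0	0.0	0.0	0.0	0.6
GH26	b-mannanase & xylanase	3.0	2.7	1.9	0.8	2.0	1.5
GH28	galacturonases	4.6	4.4	0.7	0.6	1.4	0.9
GH53	endo-1,4-b-galactanase	2.2	0.9	3.3	2.7	2.2	0.2
GH16	xyloglucanases & xyloglycosyltransferases	2.5	4.5	1.5	0.1	0.6	2.0
GH17	1,3-b-glucosidases	0.0	0.1	0.0	0.0	0.0	0.1
GH51	a-L-arabinofuranosidase	4.5	2.7	4.5	9.9	2.0	7.8
GH54	a-L-arabinofuranosidase	0.0	0.1	0.0	0.2	0.0	0.0
GH62	a-L-arabinofuranosidase	0.0	0.0	0.0	0.0	0.0	1.7
GH67	a-glucuronidase	0.2	0.5	1.9	0.0	3.3	3.6
GH74	endoglucanases & xyloglucanases	1.0	2.6	0.4	0.0	0.7	1.6
GH78	a-L-rhamnosidase	5.4	4.3	9.3	5.1	0.8	8.1
GH81	1,3-b-glucanase	0.0	0.0	0.0	0.0	0.0	0.3
GH1	b-glucosidase & other b-linked dimers	1.8	0.8	22.7	1.8	2.5	9.2
GH2	b-galactosidases & other b-linked dimers	19.7	16.8	8.9	28.5	13.6	8.6
GH3	mainly b-glucosidases	18.7	13.1	26.8	26.6	15.5	12.2
GH29	a-L-fucosidase	3.3	6.3	0.7	4.2	1.2	2.1
GH35	b-galactosidase	1.2	1.3	1.1	1.9	0.6	0.6
GH38	a-mannosidase	0.9	1.9	1.1	2.6	4.2	2.6
GH39	b-xylosidase	0.9	1.1	0.4	0.3	1.5	1.0
GH42	b-galactosidase	0.8	1.1	3.0	1.9	6.9	2.5
GH43	arabinases & xylosidases	18.5	14.8	3.7	9.3	6.6	11.3
GH52	b-xylosidase	0.0	0.0	0.0	0.0	0.3	0.0
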