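#n_cases=198
#n_controls=202
variant_id	position	carriers_cases	carriers_controls
E40K	8335323	1	8
8337000	8337000	2	0
8337027	8337027	1	0
E167K	8337155	0	1
8337250	8337250	0	1
8340030	8340030	0	1
P210P	8340185	1	0
K217X	8340204	0	1
8341802	8341802	1	0
G223R	8341945	0	1
P251T	8342029	1	0
P307P	8342288	1	0
V308M	8342289	1	0
R336C	8342373	1	3
8342438	8342438	2	0
G361S	8344630	0	1
8344771	8344771	1	0
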