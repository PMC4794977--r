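roh	chrom	startBp	endBp	nCases	nControls	chi2Printed	pPrinted	pHomTPrinted
ROH1	2	167204846	167895993	6	15	8.87	0.002	1.44e-4
ROH2	3	121016843	121689105	10	0	6.70	0.009	9.43e-6
ROH3	10	44969326	45928700	5	11	5.63	0.01	6.12e-5
ROH4	6	69734043	70381283	2	7	5.42	0.01	0.007
ROH5	9	73966521	74829925	2	7	5.42	0.01	1.60e-12
ROH6	1	217208583	218034929	7	0	4.67	0.03	0.08
ROH7	2	26036646	26765583	7	0	4.67	0.03	0.18
ROH8	2	75174688	76481471	7	0	4.67	0.03	0.03
ROH9	1	177243354	178385972	6	0	4.00	0.04	1.67e-4
ROH10	2	112182736	113192306	6	0	4.00	0.04	0.02
ROH11	2	113858688	114678121	6	0	4.00	0.04	0.83
ROH12	4	181001922	181547116	6	0	4.00	0.04	0.33
ROH13	4	182307562	182564832	6	0	4.00	0.04	0.35
ROH14	4	183848547	184539543	6	0	4.00	0.04	1.00e-8
ROH15	9	107008151	108187183	6	0	4.00	0.04	0.51
ROH16	15	96502627	98965249	6	0	4.00	0.04	3.01e-12
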