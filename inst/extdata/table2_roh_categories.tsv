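metric	category	cases	controls	orPrinted	ciPrinted	pPrinted
nRoh	<10	204	152	NA	NA	NA
nRoh	10-12	145	88	1.22	0.87-1.72	0.23
nRoh	13-15	170	127	0.99	0.73-1.36	0.98
nRoh	>15	130	64	1.55	1.05-2.18	0.02
totalMb	<14.1	153	117	NA	NA	NA
totalMb	14.1-19.4	156	114	1.04	0.74-1.47	0.79
totalMb	19.4-25.4	163	107	1.16	0.82-1.64	0.38
totalMb	>25.4	177	93	1.45	1.02-2.06	0.03
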