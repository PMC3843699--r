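pos	2	43	56	129	171	324	417	533	544	583	663	846	909	952	1075	1283	1346	1470	1879	1985	2135	2190	2481	2508	2708	2878
hapB01	16	A	C	G	T	T	C	T	C	G	G	C	T	T	G	G	C	A	G	G	A	A	G	T	A	A	A
hapB02	5	A	C	G	A	C	C	T	G	C	A	C	T	T	A	C	T	A	C	G	A	A	G	T	A	A	A
hapB03	4	T	C	C	T	T	C	A	G	G	G	C	T	C	G	G	C	A	G	G	A	A	G	T	A	A	A
hapB04	4	A	C	G	T	T	G	T	C	G	G	C	T	C	A	G	T	A	G	G	A	A	G	T	A	A	A
hapB05	4	A	C	G	A	T	C	A	G	G	A	C	T	T	A	G	T	A	G	G	A	A	G	T	A	A	A
hapB06	4	A	C	G	T	T	C	T	C	G	G	G	T	T	A	G	T	A	G	G	A	A	G	T	A	A	A
hapB07	3	A	C	C	A	C	C	A	C	C	A	C	T	T	A	G	T	A	G	G	A	A	G	T	A	A	A
hapB08	3	A	C	G	T	T	C	T	C	C	G	C	T	C	A	G	T	A	G	G	A	A	G	T	A	A	A
hapB09	3	T	C	G	T	C	C	A	G	C	G	C	T	T	G	G	T	A	G	G	A	A	G	T	A	A	A
hapB10	2	A	G	G	T	C	C	A	G	C	G	C	T	T	A	C	T	A	G	G	A	A	G	G	A	A	A
hapB11	2	A	C	G	A	C	C	T	C	C	G	C	T	T	G	G	T	A	G	G	A	G	G	T	A	A	A
hapB12	2	T	C	G	T	T	C	A	C	G	G	C	T	C	A	G	T	A	G	G	A	G	G	T	A	A	A
hapB13	2	A	C	G	A	T	C	T	G	C	G	C	T	T	G	C	T	A	C	G	A	A	T	T	A	A	A
hapB14	2	T	C	G	A	C	C	T	C	C	G	C	T	C	A	G	T	A	C	G	C	A	G	G	A	A	A
hapB15	2	A	C	G	A	T	C	A	G	C	G	C	T	C	A	G	T	A	G	G	A	A	G	T	A	A	A
hapB16	2	A	C	G	A	C	C	A	C	C	G	C	T	C	A	G	T	C	G	T	A	A	G	T	A	G	A
hapB17	1	T	C	G	A	C	C	A	C	C	G	G	T	C	A	G	T	A	G	G	A	A	G	T	A	A	A
hapB18	1	T	C	G	T	T	G	T	C	C	G	G	T	C	A	G	T	A	G	G	C	G	G	T	A	A	A
hapB19	1	T	C	G	T	T	C	T	G	G	G	C	T	C	A	G	T	C	C	G	A	A	G	T	T	A	G
hapB20	1	T	C	G	A	C	C	T	C	C	G	C	C	C	A	G	T	C	G	G	C	A	G	T	A	A	A
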