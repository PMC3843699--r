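pos	60	73	129	254	513	532	624	628	630	634	663	676	697	727	728	750	846	903	1040	1064	1075	1283	1470	1586	1635	1668	1991	2135	2190	2267	2394	2460	2708	2843	2878	2906	3080	3102	3120	3140	3160	3186	3267	3335
hapA01	6	A	C	A	C	C	G	C	A	G	T	C	G	A	G	A	A	T	T	C	T	G	C	C	T	C	T	T	A	G	T	T	T	A	A	A	C	A	A	C	A	C	A	T	A
hapA02	6	A	C	T	G	C	G	C	A	G	T	C	G	A	G	A	A	T	T	C	T	G	C	C	T	C	T	T	A	G	T	T	T	A	A	A	C	A	A	C	C	A	T	T	G
hapA03	4	A	C	T	G	C	G	C	A	G	T	C	G	A	G	A	A	C	T	C	T	C	C	C	T	C	G	T	A	G	T	T	T	A	A	A	C	A	A	C	C	A	T	C	G
hapA04	4	A	C	A	C	C	C	C	A	G	T	C	G	A	G	A	A	C	T	C	T	G	C	C	T	C	G	T	A	T	T	T	T	A	A	A	C	A	A	C	C	A	A	T	G
hapA05	3	A	C	T	G	C	G	C	T	G	T	C	G	A	G	A	A	T	T	C	T	G	C	C	T	C	G	T	A	G	T	T	T	A	A	A	C	T	A	G	C	A	A	T	G
hapA06	3	A	C	A	C	C	G	C	T	G	T	C	G	A	G	G	A	C	T	C	C	G	C	G	T	C	G	T	A	G	T	T	T	A	A	A	C	A	A	C	C	C	T	T	A
hapA07	3	A	C	A	G	C	C	C	T	G	T	C	G	A	G	A	A	T	A	C	C	G	C	C	G	C	T	T	A	G	T	T	T	A	A	A	C	A	A	C	C	C	A	C	A
hapA08	2	A	C	T	G	C	G	C	A	G	T	C	G	A	G	A	A	T	T	C	C	G	C	G	G	C	T	T	A	G	T	T	T	A	A	A	C	T	A	C	C	A	A	T	A
hapA09	2	A	C	T	G	C	G	C	T	G	T	G	G	A	G	A	A	C	T	C	C	G	C	C	T	C	G	T	A	G	T	T	T	A	A	A	C	T	A	C	C	C	A	C	G
hapA10	2	A	C	A	G	C	C	C	T	G	T	C	C	A	G	A	A	T	A	C	T	G	C	G	G	C	G	T	A	T	T	T	T	A	A	A	C	T	A	C	C	C	T	C	G
hapA11	2	A	C	A	G	C	G	C	A	G	T	C	G	A	G	A	A	T	A	C	C	G	C	C	T	C	G	T	A	T	T	T	C	A	A	A	C	T	A	C	C	C	A	T	A
hapA12	2	A	C	T	G	C	G	C	A	G	T	C	G	A	G	A	A	T	T	C	T	G	C	C	T	C	T	T	A	G	T	T	T	A	A	A	C	A	A	C	A	C	T	T	G
hapA13	2	A	C	T	G	C	G	C	A	G	T	C	G	A	G	A	A	C	T	G	C	G	C	G	T	C	G	A	A	G	T	T	T	A	A	A	C	A	A	C	C	C	T	C	G
hapA14	2	C	C	A	G	C	G	C	A	G	T	C	G	A	G	A	G	T	T	C	T	G	C	C	T	C	G	T	A	G	T	T	T	A	A	A	G	T	A	C	A	C	T	T	G
hapA15	2	A	C	A	G	A	G	C	T	G	T	C	G	A	G	A	A	T	T	C	C	G	C	C	T	C	T	T	A	G	T	T	T	A	A	A	C	T	A	C	C	C	T	T	G
hapA16	2	A	C	A	G	C	G	C	T	A	T	C	G	A	G	A	A	C	A	C	C	G	C	G	T	C	T	T	A	G	T	T	T	A	A	A	C	A	A	C	C	C	A	C	A
hapA17	1	A	C	T	C	C	G	C	T	G	T	C	G	A	G	A	A	C	T	C	C	G	C	C	T	C	T	T	A	G	T	T	T	A	A	A	C	T	C	C	A	C	T	T	A
hapA18	1	A	C	T	C	C	G	C	T	A	T	C	G	A	G	A	A	T	T	C	C	G	C	C	T	C	G	T	A	G	T	T	T	A	A	A	C	T	A	C	C	C	A	C	G
hapA19	1	A	C	A	C	C	G	C	A	G	T	C	G	A	T	A	A	T	T	C	C	G	C	C	T	C	G	A	A	G	T	T	T	A	A	A	C	A	A	C	C	C	T	T	G
hapA20	1	C	C	T	C	C	G	C	A	G	T	C	G	A	G	A	A	C	A	C	C	G	C	C	T	C	T	T	A	G	T	T	T	A	A	A	C	A	A	C	C	A	A	C	G
hapA21	1	A	C	A	G	C	C	C	A	A	T	C	G	A	G	A	A	T	T	C	T	C	C	G	T	C	G	T	A	G	T	T	T	A	A	A	C	T	A	C	C	C	T	C	G
hapA22	1	A	C	A	C	C	G	C	T	G	T	C	G	A	G	A	A	T	T	C	C	G	C	C	T	C	G	T	A	G	T	T	T	A	A	A	C	T	A	C	C	C	T	T	G
hapA23	1	A	C	A	C	C	G	C	A	G	T	C	G	A	G	G	A	T	T	C	C	G	C	C	T	G	G	T	A	G	T	T	T	A	A	A	C	T	A	C	C	C	T	C	A
hapA24	1	A	C	A	G	C	C	C	A	G	T	C	G	A	G	A	A	C	T	C	C	G	C	G	T	G	T	T	A	G	T	T	T	A	A	A	C	A	A	C	C	C	T	C	G
hapA25	1	A	C	A	G	C	G	C	A	G	T	C	G	A	G	A	A	T	T	C	T	G	T	G	T	C	T	T	A	G	T	T	T	A	A	A	C	A	A	C	A	C	A	T	G
hapA26	1	A	A	A	G	C	G	C	T	G	T	C	G	T	G	A	A	T	T	C	C	G	C	C	T	C	T	T	A	G	T	T	T	A	A	A	C	T	A	C	C	C	T	C	A
hapA27	1	A	C	A	G	C	C	C	T	G	T	C	G	A	G	A	A	T	A	C	C	G	C	G	G	C	G	A	A	G	T	T	T	A	A	A	C	A	A	C	C	C	T	T	G
hapA28	1	A	C	A	G	C	G	G	T	G	T	C	G	A	G	A	A	T	A	C	C	G	C	C	T	C	T	T	A	G	T	T	T	A	A	A	C	A	A	C	A	C	T	T	A
hapA29	1	A	C	A	G	C	G	C	A	G	T	C	G	A	G	G	A	T	T	C	C	G	C	C	T	C	G	T	G	G	T	T	T	A	A	A	C	T	A	C	C	C	A	C	G
hapA30	1	A	C	T	G	C	G	C	A	G	T	C	G	A	G	A	A	T	T	C	C	G	C	C	T	C	G	T	G	G	T	T	T	G	A	A	C	T	A	C	C	A	A	T	G
hapA31	1	A	C	A	G	C	G	C	T	G	T	C	G	A	G	G	A	T	T	C	C	C	C	C	T	C	G	T	A	G	G	T	T	G	A	A	C	A	A	C	C	C	T	T	A
hapA32	1	A	C	A	C	C	G	C	T	G	T	G	G	A	G	A	A	C	T	C	C	G	C	G	T	C	G	T	A	G	T	T	T	A	G	A	C	T	C	C	A	A	A	C	A
hapA33	1	A	A	A	G	C	C	C	A	G	G	C	G	A	G	A	A	T	T	C	C	G	C	C	T	C	T	T	A	G	T	G	T	A	A	G	C	T	A	C	C	C	T	C	A
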