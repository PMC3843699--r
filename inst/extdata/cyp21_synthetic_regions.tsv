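label	start	end
noncds	1	120
cds	121	230
noncds	231	395
cds	396	495
intron2	496	777
cds	778	937
noncds	938	1102
cds	1103	1232
noncds	1233	1397
cds	1398	1567
noncds	1568	1732
cds	1733	1872
noncds	1873	2037
cds	2038	2187
noncds	2188	2352
cds	2353	2512
noncds	2513	2677
cds	2678	2857
noncds	2858	2877
cds	2878	3065
noncds	3066	3357
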