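group	tcm	drug	votes
1	eugenol	acetaminophen	993
2	epicatechin	celecoxib	957
3	rosmarinic_acid	celecoxib	946
4	chenodeoxycholic_acid	acetaminophen	929
5	eugenol	diclofenac	912
6	eugenol	naproxen	910
7	myricetin	celecoxib	908
8	chenodeoxycholic_acid	diclofenac	898
9	chenodeoxycholic_acid	naproxen	897
10	rhein	celecoxib	894
11	anethole	naproxen	854
12	anethole	diclofenac	853
13	nobiletin	celecoxib	832
14	fisetin	celecoxib	791
15	rhein	hydroxychloroquine	770
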