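tcm	drug	dose_tcm	dose_drug	inhibition_pct	inhibition_sd	ci	pair_ci_bound
rhein	celecoxib	100	100	39.31	2.92	0.37
rhein	celecoxib	20	100	35.68	1.49	0.49
rhein	celecoxib	4	100	38.60	0.80	0.39
rhein	celecoxib	100	20	20.08	1.22	0.40
rhein	celecoxib	100	4	14.22	1.59	0.17
rhein	celecoxib	20	20	20.17	1.49	0.40
nobiletin	celecoxib	100	100	96.20	0.24	0.01
nobiletin	celecoxib	100	20	61.50	1.67	0.17
myricetin	celecoxib	100	100	64.05	0.94	0.06
myricetin	celecoxib	20	100	37.13	2.13	0.46
myricetin	celecoxib	4	100	37.96	1.58	0.41
myricetin	celecoxib	100	20	53.92	1.59	0.03
myricetin	celecoxib	100	4	49.97	0.93	0.02
fisetin	celecoxib	100	100	99.06	0.03	0.02
fisetin	celecoxib	4	100	57.80	1.89	0.88
rhein	hydroxychloroquine	100	20	86.88	0.04	0.28
epicatechin	celecoxib	NA	NA	NA	NA	NA	>1
rosmarinic_acid	celecoxib	NA	NA	NA	NA	NA	>1
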