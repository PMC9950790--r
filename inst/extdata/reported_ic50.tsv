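agent	ic50_umol_l
myricetin	>100
nobiletin	23.93
fisetin	31.19
celecoxib	>100
hydroxychloroquine	79.43
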