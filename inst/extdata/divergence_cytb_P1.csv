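"",albitextura,densitexta,maniformis,tenuitela,vittaformis,GB
albitextura,0,0.3,17.4,0,2.3,17.2
densitexta,0.3,0.3,17.4,0.3,2.6,17.2
maniformis,17.4,17.4,0,17.4,18.6,13.1
tenuitela,0,0.3,17.4,0,2.3,17.2
vittaformis,2.3,2.6,18.6,2.3,0.6,18.6
GB,17.2,17.2,13.1,17.2,18.6,0.9
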