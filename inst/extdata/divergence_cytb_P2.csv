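"",albitextura,densitexta,fiscella,maniformis,GB,Spondyliaspis
albitextura,0.3,0.3,10.5,11.6,0.3,14.8
densitexta,0.3,0,10.5,11.6,0.3,14.8
fiscella,10.5,10.5,0.6,8.4,10.5,14.8
maniformis,11.6,11.6,8.4,0,11.6,16.3
GB,0.3,0.3,10.5,11.6,0.3,14.8
Spondyliaspis,14.8,14.8,14.8,16.3,14.8,0.6
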