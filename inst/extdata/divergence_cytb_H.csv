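"",albitextura,densitexta,fiscella,tenuitela,GB,Spondyliaspis
albitextura,0.9,1.2,2.3,0.6,3.8,3.5
densitexta,1.2,0.6,1.7,0.9,3.2,3.5
fiscella,2.3,1.7,0,2,2,2.9
tenuitela,0.6,0.9,2,0.6,3.5,3.2
GB,3.8,3.2,2,3.5,0.9,4.9
Spondyliaspis,3.5,3.5,2.9,3.2,4.9,0
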