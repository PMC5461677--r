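"",albitextura,fiscella,maniformis,tenuitela,GB,Spondyliaspis
albitextura,0.9,17.2,15.1,0.9,15.4,16.9
fiscella,17.2,0.6,4.7,17.4,2.9,3.2
maniformis,15.1,4.7,0.6,15.7,1.7,3.2
tenuitela,0.9,17.4,15.7,0.3,15.7,17.2
GB,15.4,2.9,1.7,15.7,0,2
Spondyliaspis,16.9,3.2,3.2,17.2,2,0
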