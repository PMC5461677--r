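host_species,emerged_species,emerged_sex,other_species,informative,uninformative
albitextura,P1,female,No,20,40
albitextura,P2,female,No,7,3
albitextura,P2,male,No,2,0
albitextura,H,female,P2,20,5
albitextura,H,male,P2,15,2
albitextura,HH,female,No,5,5
fiscella,P1,female,No,0,1
fiscella,P2,female,No,2,0
fiscella,P2,male,No,2,0
fiscella,H,female,P2,20,7
fiscella,H,male,P2,20,6
fiscella,HH,female,No,8,1
fiscella,HH,male,P1,4,0
maniformis,P1,female,No,2,10
maniformis,P2,female,No,17,4
maniformis,P2,male,No,20,3
maniformis,HH,female,No,8,2
maniformis,HH,male,P1,4,2
tenuitela,P1,female,No,8,45
tenuitela,H,female,P2,14,0
tenuitela,H,male,P2,4,2
tenuitela,HH,female,No,5,3
GB,P1,female,No,20,162
GB,P2,female,No,20,5
GB,P2,male,No,20,4
GB,H,female,P2,20,6
GB,H,male,P2,20,6
GB,HH,female,No,8,1
GB,HH,male,P1,3,7
Spondyliaspis,P2,female,No,3,6
Spondyliaspis,P2,male,No,4,0
Spondyliaspis,H,male,P2,2,1
Spondyliaspis,HH,female,No,4,1
Spondyliaspis,HH,male,P1,2,0
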