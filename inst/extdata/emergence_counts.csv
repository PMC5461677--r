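host_species,morphospecies,sex,count
albitextura,P1,female,67
albitextura,P2,female,10
albitextura,P2,male,2
albitextura,H,female,50
albitextura,H,male,17
albitextura,HH,female,10
albitextura,HH,male,0
albitextura,Aphelinidae,female,0
densitexta,P1,female,75
densitexta,P2,female,2
densitexta,P2,male,3
densitexta,H,female,2
densitexta,H,male,2
densitexta,HH,female,0
densitexta,HH,male,0
densitexta,Aphelinidae,female,0
fiscella,P1,female,1
fiscella,P2,female,2
fiscella,P2,male,2
fiscella,H,female,59
fiscella,H,male,60
fiscella,HH,female,9
fiscella,HH,male,4
fiscella,Aphelinidae,female,0
maniformis,P1,female,12
maniformis,P2,female,29
maniformis,P2,male,21
maniformis,H,female,0
maniformis,H,male,0
maniformis,HH,female,10
maniformis,HH,male,6
maniformis,Aphelinidae,female,0
tenuitela,P1,female,53
tenuitela,P2,female,0
tenuitela,P2,male,0
tenuitela,H,female,14
tenuitela,H,male,6
tenuitela,HH,female,8
tenuitela,HH,male,0
tenuitela,Aphelinidae,female,1
vittaformis,P1,female,5
vittaformis,P2,female,0
vittaformis,P2,male,0
vittaformis,H,female,0
vittaformis,H,male,0
vittaformis,HH,female,0
vittaformis,HH,male,0
vittaformis,Aphelinidae,female,0
GB,P1,female,301
GB,P2,female,57
GB,P2,male,27
GB,H,female,26
GB,H,male,26
GB,HH,female,9
GB,HH,male,10
GB,Aphelinidae,female,0
Spondyliaspis,P1,female,0
Spondyliaspis,P2,female,9
Spondyliaspis,P2,male,4
Spondyliaspis,H,female,0
Spondyliaspis,H,male,3
Spondyliaspis,HH,female,5
Spondyliaspis,HH,male,2
Spondyliaspis,Aphelinidae,female,2
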