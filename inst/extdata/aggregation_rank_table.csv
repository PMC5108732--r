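item,gm_aij,gm_aip,median_aij,median_aip,mean_aij,mean_aip
medical,1,1,1,1,1,1
research,3,3,5,5,3,3
events,6,6,9,6,6,5
social,2,2,4,3,7,2
diagnosis,5,4,2,2,2,4
treatment,4,5,3,4,4,6
patterns,7,8,6,8,9,11
studies,11,10,7,11,5,10
results,9,9,8,9,8,8
registries,13,13,13,12,11,13
law,10,12,10,13,10,12
psychosocial,12,11,11,10,12,9
selfhelp,8,7,12,7,13,7
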