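item,block,bws_value,ahp_local_weight,bws_rank,ahp_rank,card_rank
medical,goal,1.000,0.368,1,1,1
research,goal,0.322,0.152,3,3,3
events,goal,0.000,0.117,4,4,3
social,goal,0.372,0.158,2,2,2
diagnosis,medical,0.855,0.354,2,1,1
treatment,medical,1.000,0.342,1,2,1
patterns,medical,0.000,0.142,3,3,2
studies,research,0.279,0.304,2,2,2
results,research,1.000,0.339,1,1,1
registries,research,0.000,0.184,3,3,2
law,social,0.421,0.213,2,3,2
psychosocial,social,0.000,0.220,3,2,2
selfhelp,social,1.000,0.363,1,1,1
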