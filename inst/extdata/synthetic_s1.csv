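sample_id,common_name,mtcr_recovered,mtcr_match_species,mtcr_pct_identity,paxc_recovered,paxc_match_species,paxc_pct_identity
AQ001,strawberry shortcake,yes,Acropora abrotanoides,100.000,yes,Acropora abrotanoides,99.800
AQ002,bali green slimer,yes,Acropora millepora,99.500,yes,Acropora tenuis,98.200
AQ003,oregon blue tort,yes,Acropora sp.,100.000,yes,Acropora valida,97.400
AQ004,tricolor,yes,,n/a,yes,,
AQ005,pink lemonade,yes,Acropora cf. tenuis,99.100,yes,Acropora digitifera,95.700
AQ006,red planet,yes,Acropora hyacinthus,98.700,yes,,
AQ007,green slimer,yes,Acropora millepora,100.000,no,,
AQ008,purple bonsai,yes,Acropora loripes,99.300,no,,
AQ009,blue tenuis,yes,,,no,,
AQ010,aussie stag,yes,Acropora sp.,100.000,no,,
AQ011,yellow tip,no,,,yes,Acropora yongei,100.000
AQ012,mystery frag,no,,,no,,
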