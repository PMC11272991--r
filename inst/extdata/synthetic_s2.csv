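record_id,supposed_species,excluded_singleton,matched_species
m01,Acropora florida,no,Acropora florida
m02,Acropora florida,no,Acropora florida
m03,Acropora florida,no,Acropora robusta
m04,Acropora robusta,no,Acropora robusta
m05,Acropora robusta,no,Acropora florida
m06,Acropora cervicornis,no,Acropora cervicornis
m07,Acropora palmata,no,Acropora cervicornis
m08,Acropora millepora,no,
m09,Acropora millepora,no,Acropora tenuis
m10,Acropora tenuis,no,Acropora millepora
m11,Acropora suharsonoi,yes,
m12,Acropora yongei,yes,
m13,Acropora digitifera,no,Acropora digitifera
m14,Acropora digitifera,no,Acropora cf. digitifera
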