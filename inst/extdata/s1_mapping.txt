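# logical field = column header in the per-sample two-locus table
sample_id=sample_id
mtcr_recovered=mtcr_recovered
mtcr_species=mtcr_match_species
mtcr_identity=mtcr_pct_identity
paxc_recovered=paxc_recovered
paxc_species=paxc_match_species
paxc_identity=paxc_pct_identity
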