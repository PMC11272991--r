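# logical field = column header in the per-record mitogenome table
record_id=record_id
supposed_species=supposed_species
matched_species=matched_species
excluded=excluded_singleton
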