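esi_mode,peak_pairs,identified_metabolites
positive,1243,85
negative,89,22
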