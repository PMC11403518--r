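# Tiered definitions of the two neuromodulatory networks of interest.
# Tiers are increments; readNetworks() accumulates them into nested sets
# (brainstem; brainstem+forebrain; brainstem+forebrain+cortical).
# Brainstem entries use the standard nucleus abbreviations; forebrain and
# cortical entries name the target structures. Ids must resolve against the
# ROI metadata of the dataset they are applied to.
networks:
  - name: emotional_modulatory
    tiers:
      brainstem: [PAG, VTA, LC, MedR, DR, RPO, PP, RG, RPC, CR, PB]
      forebrain: [Ch4, Ch123, thal_ventroposterior]
      cortical: [frontal_sup, frontal_med, frontal_inf, supramarginal,
                 angular, insula_ant, temporal_inf, cingulate_ant,
                 cingulate_subgenual]
  - name: emotional_motor
    tiers:
      brainstem: [PAG, SN, VTA, LC, MedR, DR, RPO, PP, RG, CR, PB, CS, Tld,
                  SC, Trm]
      forebrain: [hab, BNST, Ch123, Ch4, nacc, preoptic, hypothal_lat,
                  thal_mediodorsal]
      cortical: [orbitofrontal, insula_ant, frontal_sup_medial, cingulate_ant,
                 cingulate_subgenual, hippocampus, amygdala]
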