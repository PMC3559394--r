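quantity,value
n_conflicts_recorded,356
n_pcmc_pairs_analyzed,346
pc_consolation_only,146
pc_reconciliation_only,34
pc_consolation_and_reconciliation,56
pc_no_affiliation,110
n_focal_victims,32
observation_hours_group1,301
observation_hours_group2,152
n_scans_group1,794
n_scans_group2,411
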