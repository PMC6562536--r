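metric	count
promoters	37103
active_promoters	14007
enhancers	61570
super_enhancers	1711
broad_h3k4me3_domains	1989
deg_up_pig_vs_human	419
deg_down_pig_vs_human	621
seq_only_enhancers_regulatory_elsewhere	30073
seq_only_enhancers_total	38460
poised_promoters	9499
crc_tfs_shared_all_species	10
crc_tfs_total	26
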