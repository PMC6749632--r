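group,quadrat_id,hair_count,mean_diameter_um,total_area_um2
control,1,9,89.9,59689
control,2,10,85.1,59274
control,3,9,86.6,56286
affected,1,43,22.9,18802
affected,2,44,23.8,20348
affected,3,56,18.0,14773
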