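attribute,ranch,control
total_consumption,4064.63,720.83
total_export,1422.78,0.54
total_respiration,1737.31,314.03
total_flow_to_detritus,3180.26,2742.08
TST_published,10404.99,3777.48
total_production,4098.69,2932.48
total_primary_production,3157.37,2804.18
total_biomass,182.83,32.90
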