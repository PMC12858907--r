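fixture	quantity	value	method
toy_T1_glc10	max_biomass	10.000000000000	vertex_enumeration
toy_T1_cit100	max_biomass	0.000000000000	vertex_enumeration
crossfeeder_glc10	no_limitation_total	15.000000000000	vertex_enumeration
crossfeeder_glc10	equal_abundance_mu	5.000000000000	vertex_enumeration
crossfeeder_glc10	target_B_biomass	5.000000000000	vertex_enumeration
crossfeeder_glc10	pfba_min_import_at_15	10.000000000000	vertex_enumeration
dhp_C1	dh_total	70.000000000000	closed_form
dhp_C1	dhp_total	178.217821782178	closed_form
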