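metabolite_id	class
# amino acids
his_e	amino_acid
glu_e	amino_acid
phe_e	amino_acid
fmet_e	amino_acid
gly_e	amino_acid
pro_e	amino_acid
ala_e	amino_acid
ser_e	amino_acid
met_e	amino_acid
# organic acids
cit_e	organic_acid
ac_e	organic_acid
fum_e	organic_acid
succ_e	organic_acid
hdca_e	organic_acid
ttdca_e	organic_acid
lac_e	organic_acid
mal_e	organic_acid
inter_e	organic_acid
# carbohydrates
glc_e	carbohydrate
glc__D_e	carbohydrate
fru_e	carbohydrate
rib_e	carbohydrate
# vitamins and cofactors
thm_e	vitamin
nac_e	vitamin
vitd2_e	vitamin
btn_e	vitamin
vit_e	vitamin
# nucleotides
ade_e	nucleotide
gua_e	nucleotide
ura_e	nucleotide
cytd_e	nucleotide
ins_e	nucleotide
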