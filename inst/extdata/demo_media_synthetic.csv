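medium_id,fcs_percent,albumin_um,lipid_mg_l,notes
serum_free,0,0,0,
dmem_5fcs,5,,,
rpmi_10fcs,10,,,
calux_dcc5,5,17.3,0,charcoal-stripped serum; lipid removed
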