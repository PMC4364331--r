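gene,cell_type,sign,source
NES,pericyte_type2,+,published
NES,pericyte_type1,+,published
NES,endothelial,+,published
NES,satellite_selfrenewing,-,published
CSPG4,pericyte_type2,+,published
CSPG4,pericyte_type1,+,published
CSPG4,satellite_selfrenewing,-,published
MCAM,pericyte_type2,+,published
MCAM,pericyte_type1,+,published
MCAM,endothelial,+,published
MCAM,satellite_selfrenewing,-,published
PDGFRB,pericyte_type2,+,published
PDGFRB,pericyte_type1,+,published
PDGFRA,pericyte_type1,+,published
PDGFRA,fap,+,published
CD34,satellite_selfrenewing,+,published
CD34,satellite_committed,+,published
CD34,endothelial,+,published
CD34,fap,+,published
CD34,myoblast,-,published
CD34,adipocyte,-,published
CD34,fibrocyte,+,published
SCA1,satellite_selfrenewing,-,published
SCA1,fap,+,published
PECAM1,endothelial,+,published
PECAM1,fap,-,published
PECAM1,satellite_selfrenewing,-,published
PAX7,satellite_selfrenewing,+,published
PAX7,satellite_committed,+,published
PAX7,myoblast,-,published
PAX7,pericyte_type1,-,published
PAX7,endothelial,-,published
MYF5,satellite_committed,+,published
MYF5,myoblast,+,published
MYF5,satellite_selfrenewing,-,published
MYF5,endothelial,-,published
MYF5,fap,-,published
ITGB1,satellite_selfrenewing,+,published
ITGB1,satellite_committed,+,published
ITGB1,endothelial,-,published
CD24,preadipocyte,+,published
CD24,adipocyte,-,published
CDH5,endothelial,+,published
TEK,endothelial,+,published
SOX8,satellite_selfrenewing,+,published
SOX8,satellite_committed,+?,published
SOX8,endothelial,+,published
WISP2,fap,+?,published
WISP2,preadipocyte,+,published
WISP2,adipocyte,?,published
WISP2,fibroblast,+,published
ZNF423,fap,+?,published
ZNF423,preadipocyte,+,published
ZNF423,adipocyte,+,published
CEBPA,preadipocyte,+,published
CEBPA,adipocyte,+,published
PPARG,preadipocyte,+,published
PPARG,adipocyte,+,published
ACTA2,pericyte_type1,+,published
ACTA2,endothelial,-,published
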