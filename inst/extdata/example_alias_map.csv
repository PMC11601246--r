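raw_name,canonical_name
PanCK,Pan-Keratin
panCK,Pan-Keratin
Cytokeratin,Pan-Keratin
LCA,CD45
PTPRC,CD45
CD3e,CD3
ECAD,E-cadherin
SMA,aSMA
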