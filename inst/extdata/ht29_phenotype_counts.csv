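phenotype,abbreviation,cells
Actin blebs,AB,107
Actin dots,AD,111
Anaphase-Telophase,AT,182
Angular cell edges,ACE,73
Crescent nuclei,CN,185
Large spread cells,LSC,201
Long projections,LP,59
Metaphase,MP,563
Motile,M,190
Peas in a pod,PIP,34
Peripheral actin,PA,59
Phospho-Histone H3 dots,PHD,264
Prometaphase,PMP,345
Prophase,PP,153
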