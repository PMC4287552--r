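phenotype,abbreviation,cells
Actin fiber,AF,170
Big cells,BC,310
Condensed cells,C,338
Debris,D,219
Lamellipodia,LA,258
Metaphase,MP,186
Membrane blebbing,MB,110
Normal cells,N,542
Protrusion and elongation,P,315
Telophase,Z,97
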